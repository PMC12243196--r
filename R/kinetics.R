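#' Michaelis-Menten forward model
#'
#' `v = E0 * kcat * S / (KM + S)` with units chosen to match bench practice:
#' substrate in mM, enzyme in uM, kcat in 1/min, KM in uM, velocity in
#' mM/min. Strictly increasing and saturating in S.
#'
#' @param S substrate concentration(s), mM (> 0).
#' @param kcat turnover number, 1/min (> 0).
#' @param KM Michaelis constant, uM (> 0).
#' @param E0 enzyme concentration, uM (> 0).
#' @return initial velocity, mM/min.
#' @examples
#' mm_velocity(S = 0.093, kcat = 4.6, KM = 93, E0 = 1)  # half-saturation
#' @export
mm_velocity <- function(S, kcat, KM, E0) {
  if (any(S <= 0) || kcat <= 0 || KM <= 0 || E0 <= 0)
    stopf("S, kcat, KM and E0 must all be positive")
  (E0 * 1e-3) * kcat * S / (KM * 1e-3 + S)
}

# catalytic efficiency in 1/(M s) from kcat in 1/min and KM in uM
#' Catalytic efficiency from kcat and KM
#' @param kcat turnover number, 1/min.
#' @param KM Michaelis constant, uM.
#' @return `kcat/KM` in 1/(M s): `(kcat / 60) / (KM * 1e-6)`.
#' @export
kcat_km_from_params <- function(kcat, KM) (kcat / 60) / (KM * 1e-6)

kinetics_fit <- function(kcat, KM, kcat_over_KM, mode, rss, converged) {
  structure(list(kcat = kcat, KM = KM, kcat_over_KM = kcat_over_KM,
                 mode = mode, rss = rss, converged = converged),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  if (x$mode == "mm_fit")
    cat(sprintf("MM fit: kcat = %.3g 1/min, KM = %.3g uM, kcat/KM = %.4g 1/(M s)\n",
                x$kcat, x$KM, x$kcat_over_KM))
  else
    cat(sprintf("linear fit: kcat/KM = %.4g 1/(M s)\n", x$kcat_over_KM))
  invisible(x)
}

#' Fit the Michaelis-Menten model to an initial-rate series
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a deterministic
#' initialization: `kcat0 = max(v) / E0` and `KM0 = median(S)`. Requires at
#' least four distinct substrate concentrations and visible curvature; a
#' flat series is rejected rather than fitted, since the model is then
#' unidentifiable (KM collapses toward 0).
#'
#' @param S substrate concentrations, mM.
#' @param v initial velocities, mM/min (same length as `S`; replicates are
#'   passed as repeated concentrations).
#' @param E0 enzyme concentration, uM.
#' @param max_iter iteration cap, default 500.
#' @return a `kinetics_fit` with `mode = "mm_fit"`; `kcat` in 1/min, `KM` in
#'   uM, `kcat_over_KM` in 1/(M s) satisfying
#'   `kcat_over_KM == (kcat/60)/(KM * 1e-6)`.
#' @export
fit_mm <- function(S, v, E0, max_iter = 500) {
  if (length(S) != length(v)) stopf("S and v must have equal length")
  if (length(unique(S)) < 4) stopf("need >= 4 distinct substrate concentrations")
  if (any(S <= 0)) stopf("substrate concentrations must be positive")
  if (any(v < 0)) stopf("velocities must be non-negative")
  if (all(v == 0)) stopf("velocities are all zero")
  vm <- tapply(v, S, mean)
  if (diff(range(vm)) <= 1e-10 * max(vm))
    stopf("no curvature in the rate series (all velocities equal): Michaelis-Menten parameters are unidentifiable")
  E0_mM <- E0 * 1e-3
  start <- list(kcat = max(v) / E0_mM, KM = median(S) * 1e3)
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ E0_mM * kcat * S / (KM * 1e-3 + S),
                      data = dat, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = max_iter)),
    error = function(e) stopf("Michaelis-Menten fit failed to converge: %s",
                              conditionMessage(e)))
  info <- fit$convInfo
  if (!isTRUE(info$isConv))
    stopf("Michaelis-Menten fit did not converge after %d iterations (stop code %s: %s)",
          info$finIter %||% max_iter, info$stopCode %||% NA, info$stopMessage %||% "")
  est <- coef(fit)
  if (any(est <= 0))
    stopf("Michaelis-Menten fit converged to non-physical parameters (kcat = %.3g, KM = %.3g)",
          est[["kcat"]], est[["KM"]])
  kinetics_fit(kcat = unname(est["kcat"]), KM = unname(est["KM"]),
               kcat_over_KM = kcat_km_from_params(est[["kcat"]], est[["KM"]]),
               mode = "mm_fit", rss = sum(residuals(fit)^2), converged = TRUE)
}

#' Catalytic efficiency by linear regression for non-saturating enzymes
#'
#' When substrate saturation cannot be reached, `v` is essentially linear in
#' `S` (`v ~ (kcat/KM) * E0 * S` for `S << KM`) and only the ratio kcat/KM
#' is identifiable. The slope of a regression of v on S through the origin
#' (v = 0 at S = 0, physically), divided by E0 and converted to 1/(M s),
#' estimates it.
#'
#' @param S substrate concentrations, mM (caller asserts the linear regime).
#' @param v initial velocities, mM/min.
#' @param E0 enzyme concentration, uM.
#' @param intercept fit a free intercept instead (diagnostics only),
#'   default FALSE.
#' @return a `kinetics_fit` with `mode = "linear"` (`kcat` and `KM` are NA).
#' @export
kcat_km_linear <- function(S, v, E0, intercept = FALSE) {
  if (length(S) != length(v)) stopf("S and v must have equal length")
  if (length(S) < 3) stopf("need >= 3 points for the linear estimate")
  fit <- if (intercept) lm(v ~ S) else lm(v ~ 0 + S)
  slope <- unname(coef(fit)[["S"]])       # 1/min (mM v per mM S)
  eff <- slope / (E0 * 1e-3) * 1e3 / 60   # -> 1/(M s)
  kinetics_fit(kcat = NA_real_, KM = NA_real_, kcat_over_KM = eff,
               mode = "linear", rss = sum(residuals(fit)^2), converged = TRUE)
}

#' Read an initial-rate table from CSV
#'
#' Expected columns: `enzyme`, `replicate`, `S_mM`, `v_mM_per_min`, `E0_uM`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_rate_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("enzyme", "S_mM", "v_mM_per_min", "E0_uM")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("rate table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df
}

#' Write a table of kinetics fits as CSV
#' @param fits named list of `kinetics_fit` objects (names are enzyme ids).
#' @param path CSV output path.
#' @export
write_fit_table <- function(fits, path) {
  df <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(enzyme = nm, kcat_per_min = f$kcat, KM_uM = f$KM,
               kcat_over_KM_per_M_s = f$kcat_over_KM, mode = f$mode,
               stringsAsFactors = FALSE)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
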