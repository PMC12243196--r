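#' Configuration for a planted-subfamily protein family simulation
#'
#' Describes a star-shaped (optionally two-level) evolutionary scenario: a
#' random root sequence gives rise to one ancestor per subfamily (or per
#' supergroup, then per subfamily) by i.i.d. per-site substitution, and each
#' subfamily ancestor gives rise to its members the same way. Because the
#' model has no indels by default, expected pairwise identity is analytically
#' predictable from the divergence levels, which is what makes planted
#' structure recoverable and testable.
#'
#' @param n_subfamilies number of planted subfamilies.
#' @param subfamily_sizes integer vector, one size per subfamily.
#' @param seq_length domain length in residues.
#' @param within_divergence per-site substitution probability applied from
#'   each subfamily ancestor to its members, in `[0, 1]`.
#' @param between_divergence per-site substitution probability applied from
#'   the family root to subfamily (or supergroup) ancestors; must be at
#'   least `within_divergence`.
#' @param hierarchy optional two-level grouping: a list with elements
#'   `groups` (list of integer vectors partitioning `1:n_subfamilies` into
#'   supergroups) and `divergence` (per-site substitution probability from
#'   supergroup ancestor to subfamily ancestor, between the within and
#'   between levels).
#' @param frac_characterized fraction of members carrying an experimentally
#'   characterized activity label.
#' @param taxa character vector of taxon labels assigned round-robin.
#' @param sp_prob,tm_prob Bernoulli probabilities for the signal-peptide and
#'   transmembrane prediction flags.
#' @param seed integer seed; the simulation is bit-reproducible given it.
#' @return an object of class `family_sim_config`.
#' @export
family_sim_config <- function(n_subfamilies, subfamily_sizes,
                              seq_length = 240,
                              within_divergence = 0.18,
                              between_divergence = 0.6,
                              hierarchy = NULL,
                              frac_characterized = 0.1,
                              taxa = c("Bacteria", "Eukaryota", "Archaea"),
                              sp_prob = 0.5, tm_prob = 0.1,
                              seed = 1L) {
  if (length(n_subfamilies) != 1L || n_subfamilies < 1)
    stopf("n_subfamilies must be a positive integer")
  if (length(subfamily_sizes) != n_subfamilies)
    stopf("length(subfamily_sizes) must equal n_subfamilies")
  if (any(subfamily_sizes < 1))
    stopf("subfamily sizes must be positive")
  if (seq_length < 1)
    stopf("seq_length must be positive")
  for (p in c(within_divergence, between_divergence))
    if (p < 0 || p > 1) stopf("divergences must lie in [0, 1]")
  if (within_divergence > between_divergence)
    stopf("within_divergence must not exceed between_divergence (planting undefined)")
  if (frac_characterized < 0 || frac_characterized > 1)
    stopf("frac_characterized must lie in [0, 1]")
  if (!is.null(hierarchy)) {
    if (!is.list(hierarchy) || is.null(hierarchy$groups) || is.null(hierarchy$divergence))
      stopf("hierarchy must be a list with elements 'groups' and 'divergence'")
    flat <- sort(unlist(hierarchy$groups))
    if (!identical(as.integer(flat), seq_len(n_subfamilies)))
      stopf("hierarchy$groups must partition 1:n_subfamilies")
    if (hierarchy$divergence < within_divergence ||
        hierarchy$divergence > between_divergence)
      stopf("hierarchy divergence must lie between the within and between levels")
  }
  structure(list(n_subfamilies = as.integer(n_subfamilies),
                 subfamily_sizes = as.integer(subfamily_sizes),
                 seq_length = as.integer(seq_length),
                 within_divergence = within_divergence,
                 between_divergence = between_divergence,
                 hierarchy = hierarchy,
                 frac_characterized = frac_characterized,
                 taxa = taxa, sp_prob = sp_prob, tm_prob = tm_prob,
                 seed = as.integer(seed)),
            class = "family_sim_config")
}

# i.i.d. per-site substitution: each hit site is replaced by a uniformly
# chosen *different* residue, so p is the realized substitution probability.
mutate_seq <- function(chars, p) {
  if (p <= 0) return(chars)
  hit <- which(runif(length(chars)) < p)
  if (length(hit)) {
    cur <- match(chars[hit], AA_ALPHABET20)
    chars[hit] <- AA_ALPHABET20[(cur - 1L + sample.int(19L, length(hit), replace = TRUE)) %% 20L + 1L]
  }
  chars
}

#' Simulate a protein family with planted subfamily structure
#'
#' @param config a [family_sim_config()].
#' @return a list with `records` (a data.frame of domain records: `id`,
#'   `sequence`, `coverage` (always 1), `taxon`, `activity`, `characterized`,
#'   `sp_flag`, `tm_flag`) and `truth` (a data.frame with the planted
#'   `subfamily` and, when a hierarchy is given, `supergroup` label per id).
#' @examples
#' fam <- simulate_family(family_sim_config(3, c(5, 5, 5), seq_length = 50))
#' table(fam$truth$subfamily)
#' @export
simulate_family <- function(config) {
  if (!inherits(config, "family_sim_config"))
    stopf("config must be a family_sim_config")
  with_seed(config$seed, {
    L <- config$seq_length
    root <- sample(AA_ALPHABET20, L, replace = TRUE)
    nsf <- config$n_subfamilies
    sg_of <- rep(NA_integer_, nsf)
    anc <- vector("list", nsf)
    if (is.null(config$hierarchy)) {
      for (k in seq_len(nsf))
        anc[[k]] <- mutate_seq(root, config$between_divergence)
    } else {
      groups <- config$hierarchy$groups
      for (g in seq_along(groups)) {
        g_anc <- mutate_seq(root, config$between_divergence)
        for (k in groups[[g]]) {
          sg_of[k] <- g
          anc[[k]] <- mutate_seq(g_anc, config$hierarchy$divergence)
        }
      }
    }
    n_total <- sum(config$subfamily_sizes)
    ids <- sprintf("seq%04d", seq_len(n_total))
    sf_idx <- rep(seq_len(nsf), config$subfamily_sizes)
    seqs <- character(n_total)
    for (i in seq_len(n_total))
      seqs[i] <- paste(mutate_seq(anc[[sf_idx[i]]], config$within_divergence),
                       collapse = "")
    n_char <- round(config$frac_characterized * n_total)
    characterized <- logical(n_total)
    if (n_char > 0)
      characterized[sample.int(n_total, n_char)] <- TRUE
    activity <- ifelse(characterized, sprintf("act%02d", sf_idx), NA_character_)
    records <- data.frame(
      id = ids, sequence = seqs, coverage = 1.0,
      taxon = rep_len(config$taxa, n_total),
      activity = activity, characterized = characterized,
      sp_flag = runif(n_total) < config$sp_prob,
      tm_flag = runif(n_total) < config$tm_prob,
      stringsAsFactors = FALSE)
    truth <- data.frame(
      id = ids,
      subfamily = sprintf("sf%02d", sf_idx),
      supergroup = if (is.null(config$hierarchy)) NA_character_
                   else sprintf("sg%02d", sg_of[sf_idx]),
      activity = activity,
      stringsAsFactors = FALSE)
    attr(truth, "seq_length") <- L
    list(records = records, truth = truth)
  })
}

#' Simulate an all-vs-all hit table from planted labels
#'
#' Bypasses alignment entirely: each sequence pair is assigned a log10
#' E-value drawn from the distribution of its relation class
#' (same subfamily, same supergroup, different), and a symmetric pair of
#' directed hits is emitted whenever the sampled value falls at or below the
#' emission cutoff. Non-overlapping class intervals make the planted
#' partition exactly recoverable at any threshold between them.
#'
#' @param truth ground-truth data.frame from [simulate_family()] (columns
#'   `id`, `subfamily`, optionally `supergroup`).
#' @param evalue_model a list with per-class log10-E-value distributions:
#'   elements `same_subfamily`, `different`, and (when supergroups exist)
#'   `same_supergroup`, each either `c(lo, hi)` for a uniform draw on
#'   `[lo, hi]` or `list(mean =, sd =)` for a normal draw; smaller (more
#'   negative) means more significant.
#' @param seed integer seed.
#' @param log10_cutoff emission cutoff on log10 E-value (default -3,
#'   i.e. E-value 1e-3): pairs sampling above it yield no hit.
#' @param strict if `TRUE`, reject uniform class intervals that overlap
#'   (planted classes statistically inseparable).
#' @return a hit table data.frame in 12-column tabular order.
#' @export
simulate_hit_table <- function(truth, evalue_model, seed = 1L,
                               log10_cutoff = -3, strict = FALSE) {
  n <- nrow(truth)
  if (n < 2) return(empty_hits())
  has_sg <- "supergroup" %in% names(truth) && any(!is.na(truth$supergroup))
  classes <- c("same_subfamily", if (has_sg) "same_supergroup", "different")
  miss <- setdiff(classes, names(evalue_model))
  if (length(miss))
    stopf("evalue_model is missing class(es): %s", paste(miss, collapse = ", "))
  if (strict) {
    iv <- lapply(classes, function(cl) {
      m <- evalue_model[[cl]]
      if (is.numeric(m) && length(m) == 2) sort(m) else NULL
    })
    iv <- Filter(Negate(is.null), iv)
    if (length(iv) > 1) {
      iv <- iv[order(vapply(iv, `[`, 0, 1))]
      for (i in seq_len(length(iv) - 1))
        if (iv[[i]][2] > iv[[i + 1]][1])
          stopf("overlapping log10-E intervals make planted classes inseparable")
    }
  }
  pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pair[, 1]; j <- pair[, 2]
  rel <- ifelse(truth$subfamily[i] == truth$subfamily[j], "same_subfamily",
         ifelse(has_sg & !is.na(truth$supergroup[i]) &
                truth$supergroup[i] == truth$supergroup[j],
                "same_supergroup", "different"))
  L <- attr(truth, "seq_length") %||% 240L
  with_seed(seed, {
    log10e <- numeric(length(rel))
    for (cl in classes) {
      k <- which(rel == cl)
      if (!length(k)) next
      m <- evalue_model[[cl]]
      log10e[k] <- if (is.list(m)) stats::rnorm(length(k), m$mean, m$sd)
                   else runif(length(k), min(m), max(m))
    }
    keep <- log10e <= log10_cutoff
    if (!any(keep)) return(empty_hits())
    i <- i[keep]; j <- j[keep]; log10e <- log10e[keep]; rel <- rel[keep]
    pid <- c(same_subfamily = 75, same_supergroup = 45, different = 25)[rel]
    ev <- 10^log10e
    bits <- log2(as.numeric(L) * L) - log10e / log10(2)
    one_way <- function(a, b) data.frame(
      query_id = truth$id[a], subject_id = truth$id[b],
      identity_pct = unname(pid), aln_length = L,
      mismatches = as.integer(round(L * (1 - pid / 100))),
      gap_openings = 0L, qstart = 1L, qend = L, sstart = 1L, send = L,
      evalue = ev, bitscore = round(bits, 1), stringsAsFactors = FALSE)
    out <- rbind(one_way(i, j), one_way(j, i))
    out[order(out$query_id, out$subject_id), , drop = FALSE]
  })
}
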