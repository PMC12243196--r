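#' @useDynLib ssnsubfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median coef lm residuals runif rbinom setNames
#' @importFrom utils read.delim write.table read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

AA_ALPHABET20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so simulations never perturb user code.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

assert_records <- function(records) {
  if (!is.data.frame(records))
    stopf("records must be a data.frame of domain records")
  needed <- c("id", "sequence")
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stopf("records is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(records$id))
    stopf("record ids must be unique")
  if (any(!nzchar(records$sequence)))
    stopf("sequences must be non-empty")
  if ("coverage" %in% names(records)) {
    cv <- records$coverage
    if (any(!is.na(cv) & (cv < 0 | cv > 1)))
      stopf("coverage must lie in [0, 1]")
  }
  invisible(records)
}

# 12 columns of BLAST/DIAMOND tabular output (outfmt 6), in order.
HIT_COLUMNS <- c("query_id", "subject_id", "identity_pct", "aln_length",
                 "mismatches", "gap_openings", "qstart", "qend",
                 "sstart", "send", "evalue", "bitscore")

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             identity_pct = numeric(), aln_length = integer(),
             mismatches = integer(), gap_openings = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

assert_hits <- function(hits) {
  if (!is.data.frame(hits))
    stopf("hits must be a data.frame")
  miss <- setdiff(c("query_id", "subject_id", "evalue"), names(hits))
  if (length(miss))
    stopf("hits is missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(hits) && any(hits$evalue <= 0))
    stopf("all E-values must be strictly positive")
  invisible(hits)
}
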