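#' Filter domain records by profile coverage
#'
#' Keeps records whose catalytic-domain sequence covers at least `min_cov` of
#' the family profile HMM. The comparison is inclusive (`coverage >= min_cov`)
#' and input order is preserved.
#'
#' @param records data.frame of domain records with a `coverage` column.
#' @param min_cov minimum coverage fraction, default 0.5.
#' @return the filtered data.frame.
#' @export
filter_by_coverage <- function(records, min_cov = 0.5) {
  if (!nrow(records)) return(records)
  assert_records(records)
  if (!"coverage" %in% names(records))
    stopf("records must carry a 'coverage' column")
  records[!is.na(records$coverage) & records$coverage >= min_cov, , drop = FALSE]
}

#' Global-alignment sequence identity
#'
#' Identity is the number of identical residue pairs in the optimal global
#' alignment (match = 1, mismatch = 0, unit cost per gapped position; among
#' score-optimal alignments the match-richest is used) divided by the length
#' of the shorter sequence — the CD-HIT convention, so that a fragment fully
#' contained in a longer sequence scores 1.
#'
#' @param a,b amino-acid strings (non-empty).
#' @param gap_cost linear gap cost per gapped position, default 1.
#' @return identity fraction in `[0, 1]`; symmetric in its arguments.
#' @examples
#' pairwise_identity("PEPTIDE", "PEPTIDE")  # 1
#' pairwise_identity("AAAA", "CCCC")        # 0
#' @export
pairwise_identity <- function(a, b, gap_cost = 1) {
  if (!nzchar(a) || !nzchar(b))
    stopf("sequences must be non-empty")
  .nw_identity_matches(a, b, gap_cost) / min(nchar(a), nchar(b))
}

# unique integer keys of all k-mers of a sequence (20-letter alphabet)
kmer_keys <- function(s, k = 4L) {
  idx <- match(strsplit(s, "")[[1]], AA_ALPHABET20)
  idx[is.na(idx)] <- 0L  # X and friends never match
  n <- length(idx) - k + 1L
  if (n < 1L) return(integer(0))
  key <- integer(n)
  for (p in seq_len(k)) key <- key * 21L + idx[p:(p + n - 1L)]
  unique(key)
}

#' Greedy incremental redundancy clustering
#'
#' Emulates the deterministic core of CD-HIT: records are sorted by
#' decreasing sequence length (ties broken by id, lexicographically) and
#' processed in order; each record joins the first existing cluster whose
#' *representative* (the cluster founder) it matches at identity >=
#' `identity_threshold`, otherwise it founds a new cluster. Downstream SSN
#' analysis operates on the representatives only.
#'
#' @param records data.frame of domain records with unique ids.
#' @param identity_threshold identity fraction in `(0, 1]`, default 0.8.
#' @param kmer_screen if `TRUE`, skip the alignment for candidate pairs that
#'   share no 4-mer (sequences at >= 80 percent ungapped identity over
#'   typical domain lengths always share one, so the screen is effectively
#'   lossless there); `FALSE` (the default) aligns every candidate pair
#'   exactly.
#' @return an object of class `redundancy_clustering`: a list with
#'   `clusters` (named list, representative id -> member ids including the
#'   representative), `representatives`, `identity_threshold`.
#' @export
cluster_redundancy <- function(records, identity_threshold = 0.8,
                               kmer_screen = FALSE) {
  assert_records(records)
  if (identity_threshold <= 0 || identity_threshold > 1)
    stopf("identity_threshold must lie in (0, 1]")
  ord <- order(-nchar(records$sequence), records$id)
  ids <- records$id[ord]
  seqs <- records$sequence[ord]
  kmers <- if (kmer_screen) lapply(seqs, kmer_keys) else NULL
  rep_ids <- character(0)
  rep_seqs <- character(0)
  rep_kmers <- list()
  members <- list()
  for (k in seq_along(ids)) {
    placed <- FALSE
    if (length(rep_ids)) {
      for (r in seq_along(rep_ids)) {
        if (kmer_screen && !any(kmers[[k]] %in% rep_kmers[[r]])) next
        if (pairwise_identity(seqs[k], rep_seqs[r]) >= identity_threshold) {
          members[[r]] <- c(members[[r]], ids[k])
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, ids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
      if (kmer_screen) rep_kmers[[length(rep_ids)]] <- kmers[[k]]
      members <- c(members, list(ids[k]))
    }
  }
  names(members) <- rep_ids
  structure(list(clusters = members, representatives = rep_ids,
                 identity_threshold = identity_threshold),
            class = "redundancy_clustering")
}

#' @export
print.redundancy_clustering <- function(x, ...) {
  cat(sprintf("redundancy clustering: %d members in %d clusters (identity >= %g)\n",
              sum(lengths(x$clusters)), length(x$clusters), x$identity_threshold))
  invisible(x)
}

#' @describeIn cluster_redundancy flatten a clustering to a two-column
#'   data.frame (`member_id`, `representative_id`).
#' @param x a `redundancy_clustering` object.
#' @param ... unused.
#' @export
as.data.frame.redundancy_clustering <- function(x, ...) {
  data.frame(member_id = unlist(x$clusters, use.names = FALSE),
             representative_id = rep(names(x$clusters), lengths(x$clusters)),
             stringsAsFactors = FALSE)
}
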