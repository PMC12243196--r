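#' Scoring parameters for local alignment and E-value statistics
#'
#' Defaults are the standard gapped-BLOSUM62 settings (gap open 11, extend 1,
#' Karlin-Altschul lambda = 0.267, K = 0.041). Only the *ordering* of
#' E-values matters for SSN thresholding, and any monotone score-to-E map
#' preserves it, so these defaults are appropriate even when the hits being
#' emulated came from another aligner.
#'
#' @param matrix substitution matrix name (resolved via `Biostrings`),
#'   default `"BLOSUM62"`.
#' @param gap_open,gap_extend affine gap penalties; a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param lambda,K Karlin-Altschul scale and prefactor (both > 0).
#' @param search_space_mode `"database"` (E = m * N with N the total database
#'   residues, external-aligner-like; the default) or `"pairwise"`
#'   (E = m * n for the two sequences at hand).
#' @return an object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041,
                           search_space_mode = c("database", "pairwise")) {
  if (lambda <= 0 || K <= 0) stopf("lambda and K must be positive")
  submat <- tryCatch({
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    get(matrix, envir = e)
  }, warning = function(w) stopf("unknown substitution matrix '%s'", matrix),
     error = function(e) stopf("unknown substitution matrix '%s'", matrix))
  structure(list(matrix_name = matrix, submat = submat,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 search_space_mode = match.arg(search_space_mode)),
            class = "scoring_params")
}

seq_to_indices <- function(s, submat) {
  idx <- match(strsplit(s, "")[[1]], rownames(submat))
  if (anyNA(idx))
    stopf("sequence contains residue(s) absent from the substitution matrix: %s",
          paste(unique(strsplit(s, "")[[1]][is.na(idx)]), collapse = ", "))
  idx
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment score under affine gaps (Gotoh algorithm),
#' computed by the package's compiled aligner. The score is symmetric in the
#' two sequences and never negative; when no residue pair scores positively
#' the optimal alignment is empty and the score is 0.
#'
#' @param a,b amino-acid strings.
#' @param params a [scoring_params()].
#' @return a list: `score`, `qstart`, `qend`, `sstart`, `send`, `matches`,
#'   `mismatches`, `gapopens`, `aln_length` (0/empty span when score is 0).
#' @export
smith_waterman <- function(a, b, params = scoring_params()) {
  if (!nzchar(a) || !nzchar(b)) stopf("sequences must be non-empty")
  .sw_align(seq_to_indices(a, params$submat), seq_to_indices(b, params$submat),
            params$submat, params$gap_open, params$gap_extend)
}

#' Convert a raw alignment score to a bitscore and E-value
#'
#' Karlin-Altschul statistics: `bitscore = (lambda * S - ln K) / ln 2` and
#' `evalue = m * n * 2^(-bitscore)`, equivalently `K * m * n * exp(-lambda * S)`.
#' The E-value is strictly decreasing in the score and exactly linear in the
#' search space `m * n`.
#'
#' @param raw_score alignment score in matrix units (>= 0).
#' @param m query length in residues.
#' @param n subject length, or total database residues in database mode.
#' @param params a [scoring_params()].
#' @return list with `bitscore` and `evalue`.
#' @export
score_to_evalue <- function(raw_score, m, n, params = scoring_params()) {
  bits <- (params$lambda * raw_score - log(params$K)) / log(2)
  list(bitscore = bits, evalue = m * n * 2^(-bits))
}

#' All-vs-all local alignment hit table
#'
#' Aligns every unordered pair of records once and emits both directed hits
#' whenever the pair's better-direction E-value is at or below the emission
#' cutoff; self-hits are never emitted. Deterministic.
#'
#' @param records data.frame of domain records (>= 2 rows).
#' @param params a [scoring_params()].
#' @param evalue_cutoff emission cutoff, default 1e-3.
#' @return hit table data.frame in 12-column tabular order.
#' @export
all_vs_all <- function(records, params = scoring_params(), evalue_cutoff = 1e-3) {
  assert_records(records)
  n_rec <- nrow(records)
  if (n_rec < 2) return(empty_hits())
  lens <- nchar(records$sequence)
  N_db <- sum(as.numeric(lens))
  idx_list <- lapply(records$sequence, seq_to_indices, submat = params$submat)
  rows <- vector("list", n_rec * (n_rec - 1) / 2)
  nr <- 0L
  for (i in seq_len(n_rec - 1)) {
    for (j in (i + 1):n_rec) {
      al <- .sw_align(idx_list[[i]], idx_list[[j]], params$submat,
                      params$gap_open, params$gap_extend)
      n_i <- if (params$search_space_mode == "database") N_db else lens[j]
      n_j <- if (params$search_space_mode == "database") N_db else lens[i]
      e_ij <- score_to_evalue(al$score, lens[i], n_i, params)
      e_ji <- score_to_evalue(al$score, lens[j], n_j, params)
      if (min(e_ij$evalue, e_ji$evalue) > evalue_cutoff) next
      pid <- if (al$aln_length > 0) 100 * al$matches / al$aln_length else 0
      nr <- nr + 1L
      rows[[nr]] <- data.frame(
        query_id = records$id[c(i, j)], subject_id = records$id[c(j, i)],
        identity_pct = pid, aln_length = al$aln_length,
        mismatches = al$mismatches, gap_openings = al$gapopens,
        qstart = c(al$qstart, al$sstart), qend = c(al$qend, al$send),
        sstart = c(al$sstart, al$qstart), send = c(al$send, al$qend),
        evalue = c(e_ij$evalue, e_ji$evalue),
        bitscore = c(e_ij$bitscore, e_ji$bitscore),
        stringsAsFactors = FALSE)
    }
  }
  if (nr == 0L) return(empty_hits())
  do.call(rbind, rows[seq_len(nr)])
}

#' Read a 12-column BLAST/DIAMOND tabular hit file
#'
#' Expects tab-separated `qseqid sseqid pident length mismatch gapopen qstart
#' qend sstart send evalue bitscore` rows; lines starting with `#` are
#' skipped. Self-hits are dropped and zero E-values are mapped to a floor so
#' that log10 transforms stay finite.
#'
#' @param path file path.
#' @param evalue_floor replacement for E-values printed as 0, default 1e-300.
#' @return hit table data.frame.
#' @export
read_hits_tabular <- function(path, evalue_floor = 1e-300) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stopf("malformed hit line %d: expected 12 tab-separated columns, found %d",
          lineno[which(nf != 12L)[1]], nf[nf != 12L][1])
  m <- do.call(rbind, parts)
  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(m[, col]))
    if (anyNA(v))
      stopf("non-numeric %s at hit line %d", what, lineno[which(is.na(v))[1]])
    v
  }
  hits <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = num(3, "identity"), aln_length = as.integer(num(4, "length")),
    mismatches = as.integer(num(5, "mismatch")),
    gap_openings = as.integer(num(6, "gapopen")),
    qstart = as.integer(num(7, "qstart")), qend = as.integer(num(8, "qend")),
    sstart = as.integer(num(9, "sstart")), send = as.integer(num(10, "send")),
    evalue = num(11, "evalue"), bitscore = num(12, "bitscore"),
    stringsAsFactors = FALSE)
  hits$evalue[hits$evalue <= 0] <- evalue_floor
  hits[hits$query_id != hits$subject_id, , drop = FALSE]
}

#' Write a hit table in 12-column tabular format
#'
#' @param hits hit table data.frame as produced by [all_vs_all()] or
#'   [simulate_hit_table()].
#' @param path output file path.
#' @export
write_hits_tabular <- function(hits, path) {
  assert_hits(hits)
  out <- hits[, HIT_COLUMNS]
  out$evalue <- format(out$evalue, scientific = TRUE, digits = 15, trim = TRUE)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
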