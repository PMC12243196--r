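#' Read a protein family from FASTA plus a metadata TSV
#'
#' The metadata table is joined on `id`; recognized columns are `coverage`,
#' `taxon`, `activity`, `characterized`, `sp_flag`, `tm_flag` (and any
#' ground-truth columns, which are carried along untouched).
#'
#' @param fasta path to an amino-acid FASTA file.
#' @param meta optional path to a tab-separated metadata table with an `id`
#'   column.
#' @return a data.frame of domain records.
#' @export
read_family <- function(fasta, meta = NULL) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  records <- data.frame(id = ids, sequence = as.character(aa),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL
  if (!is.null(meta)) {
    md <- read.delim(meta, stringsAsFactors = FALSE)
    if (!"id" %in% names(md)) stopf("metadata table needs an 'id' column")
    records <- merge(records, md, by = "id", all.x = TRUE, sort = FALSE)
  }
  assert_records(records)
}

#' Write a protein family as FASTA plus a metadata TSV
#'
#' @param records data.frame of domain records.
#' @param fasta output FASTA path.
#' @param meta optional output path for the metadata TSV (all non-sequence
#'   columns).
#' @param truth optional ground-truth data.frame merged into the metadata on
#'   `id` (adds e.g. `subfamily`/`supergroup` truth columns).
#' @export
write_family <- function(records, fasta, meta = NULL, truth = NULL) {
  assert_records(records)
  aa <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(aa, fasta)
  if (!is.null(meta)) {
    md <- records[, setdiff(names(records), "sequence"), drop = FALSE]
    if (!is.null(truth)) {
      keep <- c("id", setdiff(names(truth), names(md)))
      md <- merge(md, truth[, keep, drop = FALSE], by = "id", all.x = TRUE,
                  sort = FALSE)
    }
    write.table(md, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' Write a redundancy clustering as a two-column TSV
#' @param clustering a `redundancy_clustering`.
#' @param path output path (`member_id`, `representative_id`).
#' @export
write_clustering_tsv <- function(clustering, path) {
  write.table(as.data.frame(clustering), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write subfamily membership as TSV
#' @param partition a `subfamily_partition`.
#' @param path output path (`member_id`, `representative_id`,
#'   `subfamily_id`, `status`).
#' @export
write_membership_tsv <- function(partition, path) {
  write.table(partition$membership, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
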