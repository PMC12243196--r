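run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("stage '%s' failed: %s", stage, conditionMessage(e)))
}

#' Run the full subfamily-delineation pipeline
#'
#' Orchestrates coverage filtering, redundancy clustering, all-vs-all
#' similarity (internal aligner, a supplied hit table, or a hit file),
#' the closeness-centrality threshold sweep, threshold selection, rule-based
#' partitioning, expansion to full membership, split-tree construction, and
#' the functional-homogeneity and secretion summaries. Deterministic given
#' its configuration.
#'
#' @param config a list with entries:
#'   \describe{
#'     \item{records / fasta + meta}{input domain records, either in memory
#'       or as FASTA plus metadata-TSV paths (see [read_family()]).}
#'     \item{hits / hits_path}{optional precomputed all-vs-all hit table
#'       (data.frame, or 12-column tabular file); when absent the internal
#'       aligner is run on the representatives.}
#'     \item{min_cov}{coverage filter, default 0.5.}
#'     \item{identity_threshold}{redundancy threshold, default 0.8.}
#'     \item{kmer_screen}{skip alignment of candidate pairs sharing no
#'       4-mer during redundancy clustering, default FALSE.}
#'     \item{exponents}{sweep grid, default `20:99`.}
#'     \item{min_size}{release size, default 30.}
#'     \item{min_delta}{peak sensitivity, default 0.01.}
#'     \item{scoring}{a [scoring_params()] for the internal aligner.}
#'     \item{evalue_cutoff}{emission cutoff for the internal aligner,
#'       default 1e-3.}
#'     \item{taxon_grouping}{optional taxon-to-group mapping.}
#'   }
#' @param verbose log per-stage counts via `message()`, default TRUE.
#' @return a list: `records`, `clustering`, `hits`, `profile`, `peaks`,
#'   `selected_exponent`, `partition` (expanded), `split_tree` (NULL when
#'   fewer than two tree exponents exist), `homogeneity`, `secretion`,
#'   `counts`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  records <- run_stage("seq_prep", {
    r <- config$records
    if (is.null(r) && !is.null(config$fasta))
      r <- read_family(config$fasta, config$meta)
    if (is.null(r) || !nrow(r)) stopf("no input records")
    assert_records(r)
    filter_by_coverage(r, config$min_cov %||% 0.5)
  })
  if (!nrow(records))
    run_stage("seq_prep", stopf("no records pass the coverage filter"))
  say("seq_prep: %d records pass the coverage filter", nrow(records))
  clustering <- run_stage("redundancy", {
    cluster_redundancy(records, config$identity_threshold %||% 0.8,
                       kmer_screen = isTRUE(config$kmer_screen))
  })
  reps <- records[match(clustering$representatives, records$id), , drop = FALSE]
  say("redundancy: %d representatives from %d records", nrow(reps), nrow(records))
  hits <- run_stage("similarity", {
    h <- config$hits
    if (is.null(h) && !is.null(config$hits_path))
      h <- read_hits_tabular(config$hits_path)
    if (is.null(h)) {
      h <- all_vs_all(reps, config$scoring %||% scoring_params(),
                      config$evalue_cutoff %||% 1e-3)
    } else {
      assert_hits(h)
      h <- h[h$query_id %in% reps$id & h$subject_id %in% reps$id, , drop = FALSE]
    }
    h
  })
  say("similarity: %d directed hits among representatives", nrow(hits))
  exponents <- config$exponents %||% 20:99
  min_size <- config$min_size %||% 30
  profile <- run_stage("sweep", {
    sweep_thresholds(hits, exponents, node_ids = reps$id, min_size = min_size)
  })
  peaks <- detect_peaks(profile, config$min_delta %||% 0.01)
  selected <- select_threshold(profile)
  say("sweep: %d thresholds, %d peak(s), selected exponent %d (W = %.4f)",
      nrow(profile), length(peaks), selected, max(profile$W))
  partition <- run_stage("partition", {
    g <- build_ssn(hits, selected, node_ids = reps$id)
    p <- partition_at_threshold(g, reps, min_size = min_size)
    expand_to_full(p, clustering)
  })
  say("partition: %d released, %d withheld, %d singleton(s)",
      sum(partition$subfamilies$status == "released"),
      sum(partition$subfamilies$status == "withheld"),
      length(partition$non_subclassified))
  tree_exp <- sort(unique(c(peaks, selected)))
  split_tree <- if (length(tree_exp) >= 2)
    run_stage("split_tree", build_split_tree(hits, tree_exp, node_ids = reps$id,
                                             records = reps))
  else NULL
  homogeneity <- run_stage("reports", functional_homogeneity(partition, records))
  secretion <- if (all(c("sp_flag", "tm_flag", "taxon") %in% names(records)))
    run_stage("reports", secretion_summary(partition, records,
                                           config$taxon_grouping))
  else NULL
  list(records = records, clustering = clustering, hits = hits,
       profile = profile, peaks = peaks, selected_exponent = selected,
       partition = partition, split_tree = split_tree,
       homogeneity = homogeneity, secretion = secretion,
       counts = c(n_input = nrow(records), n_representatives = nrow(reps),
                  n_hits = nrow(hits), selected_exponent = selected,
                  n_released = sum(partition$subfamilies$status == "released"),
                  n_withheld = sum(partition$subfamilies$status == "withheld"),
                  n_singletons = length(partition$non_subclassified)))
}
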