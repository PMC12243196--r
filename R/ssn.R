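# Best (smallest) log10 E-value per unordered pair, as a data.frame
# (from, to, log10e). The better of the two directed hits decides edge
# membership; self-hits are ignored.
pair_best_log10e <- function(hits) {
  hits <- hits[hits$query_id != hits$subject_id, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(from = character(), to = character(), log10e = numeric(),
                      stringsAsFactors = FALSE))
  a <- pmin(hits$query_id, hits$subject_id)
  b <- pmax(hits$query_id, hits$subject_id)
  key <- paste(a, b, sep = "\r")
  best <- tapply(log10(hits$evalue), key, min)
  ab <- strsplit(names(best), "\r", fixed = TRUE)
  data.frame(from = vapply(ab, `[`, "", 1), to = vapply(ab, `[`, "", 2),
             log10e = as.numeric(best), stringsAsFactors = FALSE)
}

edge_present <- function(log10e, exponent, edge_rule) {
  # tolerance absorbs log10() round-off at exact powers of ten
  if (edge_rule == "le") log10e <= -exponent + 1e-9 else log10e < -exponent - 1e-9
}

#' Build a sequence similarity network at one E-value threshold
#'
#' Nodes are sequence ids; an undirected, unweighted edge joins u and v iff
#' the better of their two directed E-values is at or below `10^-exponent`.
#' Every id is present as a node even when isolated, so graphs across a
#' threshold sweep share one node set.
#'
#' @param hits hit table data.frame.
#' @param threshold_exponent positive integer e, meaning cutoff `10^-e`.
#' @param node_ids optional character vector fixing the node set (defaults
#'   to all ids appearing in `hits`).
#' @param edge_rule `"le"` (E-value at least as good as the cutoff counts;
#'   default) or `"lt"` (strictly better).
#' @return an `igraph` graph with graph attribute `threshold_exponent`.
#' @export
build_ssn <- function(hits, threshold_exponent, node_ids = NULL,
                      edge_rule = c("le", "lt")) {
  edge_rule <- match.arg(edge_rule)
  assert_hits(hits)
  if (threshold_exponent < 1) stopf("threshold_exponent must be >= 1")
  pairs <- pair_best_log10e(hits)
  if (is.null(node_ids))
    node_ids <- sort(unique(c(hits$query_id, hits$subject_id)))
  keep <- edge_present(pairs$log10e, threshold_exponent, edge_rule)
  g <- igraph::graph_from_data_frame(pairs[keep, c("from", "to"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = node_ids))
  g <- igraph::set_graph_attr(g, "threshold_exponent", as.integer(threshold_exponent))
  g
}

#' Closeness centrality within connected components
#'
#' For a node v in a component of size `n_C >= 2`,
#' `C(v) = (n_C - 1) / sum of shortest-path distances from v` (unweighted
#' paths, distances taken within the component only). Isolated nodes have
#' closeness 0 by convention, matching the behaviour of the common network
#' libraries on disconnected graphs.
#'
#' @param graph an SSN graph from [build_ssn()] (any `igraph` graph works).
#' @param nodes optional node names to report; defaults to all nodes.
#' @return named numeric vector of closeness values in `[0, 1]`.
#' @export
closeness_centrality <- function(graph, nodes = NULL) {
  all_names <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- all_names
  if (!all(nodes %in% all_names))
    stopf("node(s) absent from graph: %s",
          paste(setdiff(nodes, all_names), collapse = ", "))
  comp <- igraph::components(graph)
  out <- setNames(numeric(length(all_names)), all_names)
  for (ci in which(comp$csize >= 2)) {
    members <- all_names[comp$membership == ci]
    d <- igraph::distances(graph, v = members, to = members)
    out[members] <- (length(members) - 1) / rowSums(d)
  }
  out[nodes]
}

#' Weighted average closeness centrality of a network's components
#'
#' The component-size-weighted mean of per-component mean closeness, which is
#' identical to the plain mean over all nodes of their within-component
#' closeness. This is the criterion scored across the E-value threshold
#' sweep: it approaches 1 when components are tight (clique-like) and is
#' dragged down by stringy components and by singletons (closeness 0).
#'
#' @param graph an SSN graph.
#' @return a number in `[0, 1]`.
#' @export
weighted_avg_closeness <- function(graph) {
  if (igraph::vcount(graph) == 0) stopf("graph has no nodes")
  mean(closeness_centrality(graph))
}

#' Sweep E-value thresholds and profile the network criterion
#'
#' Builds one SSN per threshold exponent and records the weighted average
#' closeness centrality, the number of connected components, and the number
#' of nodes in components too small to be released (below `min_size`). The
#' default grid, exponents 20 through 99, yields exactly 80 networks
#' spanning cutoffs 1e-20 .. 1e-99.
#'
#' @param hits hit table data.frame (may be empty if `node_ids` is given:
#'   the profile is then all-singleton with W = 0).
#' @param exponents strictly increasing integer vector, default `20:99`.
#' @param node_ids optional fixed node set.
#' @param min_size release size used for the small-component node count,
#'   default 30.
#' @param edge_rule see [build_ssn()].
#' @return a data.frame of class `centrality_profile` with columns
#'   `exponent`, `W`, `n_components`, `n_unassignable`.
#' @export
sweep_thresholds <- function(hits, exponents = 20:99, node_ids = NULL,
                             min_size = 30, edge_rule = c("le", "lt")) {
  edge_rule <- match.arg(edge_rule)
  assert_hits(hits)
  if (length(exponents) < 1 || any(diff(exponents) <= 0))
    stopf("exponents must be strictly increasing")
  if (is.null(node_ids))
    node_ids <- sort(unique(c(hits$query_id, hits$subject_id)))
  pairs <- pair_best_log10e(hits)
  W <- ncomp <- nun <- numeric(length(exponents))
  for (k in seq_along(exponents)) {
    keep <- edge_present(pairs$log10e, exponents[k], edge_rule)
    if (length(node_ids) == 0) {
      W[k] <- 0; ncomp[k] <- 0; nun[k] <- 0
      next
    }
    g <- igraph::graph_from_data_frame(pairs[keep, c("from", "to"), drop = FALSE],
                                       directed = FALSE,
                                       vertices = data.frame(name = node_ids))
    comp <- igraph::components(g)
    W[k] <- weighted_avg_closeness(g)
    ncomp[k] <- comp$no
    nun[k] <- sum(comp$csize[comp$csize < min_size])
  }
  structure(data.frame(exponent = as.integer(exponents), W = W,
                       n_components = as.integer(ncomp),
                       n_unassignable = as.integer(nun)),
            class = c("centrality_profile", "data.frame"))
}

#' Detect peaks in a centrality profile
#'
#' A threshold exponent qualifies as a peak when the criterion rises by at
#' least `min_delta` relative to the immediately preceding (less stringent)
#' exponent — a marked increase between two consecutive thresholds signals
#' the separation of large groups.
#'
#' @param profile a `centrality_profile` from [sweep_thresholds()].
#' @param min_delta minimum forward increase, default 0.01.
#' @return integer vector of peak exponents, in sweep order.
#' @export
detect_peaks <- function(profile, min_delta = 0.01) {
  if (nrow(profile) < 2) stopf("profile needs at least 2 points")
  idx <- which(diff(profile$W) >= min_delta) + 1L
  profile$exponent[idx]
}

#' Select the division threshold from a centrality profile
#'
#' Returns the exponent with the maximal weighted average closeness
#' centrality; ties are broken toward the smaller exponent (the less
#' stringent threshold), so a plateau maximum selects its first point.
#'
#' @param profile a `centrality_profile`.
#' @return the selected integer exponent.
#' @export
select_threshold <- function(profile) {
  if (!nrow(profile)) stopf("profile is empty")
  profile$exponent[which.max(profile$W)]
}

#' Write a centrality profile as TSV
#' @param profile a `centrality_profile`.
#' @param path output path.
#' @export
write_profile_tsv <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an SSN as an edge-list TSV
#' @param graph an SSN graph.
#' @param path output path.
#' @export
write_edgelist_tsv <- function(graph, path) {
  el <- igraph::as_edgelist(graph)
  write.table(el, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
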