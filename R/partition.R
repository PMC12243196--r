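#' Partition an SSN into released and withheld subfamilies
#'
#' Every connected component of size >= 2 is a candidate subfamily. A
#' candidate is *released* when it holds at least `min_size` representatives
#' or at least one experimentally characterized member; smaller
#' uncharacterized candidates are *withheld* (kept traceable for future
#' release rather than silently merged away). Singletons, and for summary
#' purposes withheld members too, count as non-subclassified. Stable ids are
#' assigned by decreasing size, ties broken by the smallest member id.
#'
#' @param graph SSN graph at the selected threshold.
#' @param records data.frame of domain records covering the graph's nodes
#'   (needs `characterized`; `activity` used when present).
#' @param min_size release size, default 30 representatives.
#' @return an object of class `subfamily_partition`: list with
#'   `threshold_exponent`, `subfamilies` (data.frame: `subfamily_id`,
#'   `status`, `n_representatives`, `n_full`, `n_characterized`,
#'   `modal_activity`), `membership` (data.frame: `member_id`,
#'   `representative_id`, `subfamily_id`, `status`; initially full = reps),
#'   `non_subclassified` (singleton ids), `expanded` (logical).
#' @export
partition_at_threshold <- function(graph, records, min_size = 30) {
  assert_records(records)
  nodes <- igraph::V(graph)$name
  if (!all(nodes %in% records$id))
    stopf("graph nodes absent from records: %s",
          paste(utils::head(setdiff(nodes, records$id), 5), collapse = ", "))
  chr <- setNames(records$characterized %||% logical(nrow(records)), records$id)
  chr[is.na(chr)] <- FALSE
  comp <- igraph::components(graph)
  groups <- split(nodes, comp$membership)
  sizes <- lengths(groups)
  cand <- groups[sizes >= 2]
  singletons <- unlist(groups[sizes == 1], use.names = FALSE) %||% character(0)
  if (length(cand)) {
    n_chr <- vapply(cand, function(m) sum(chr[m]), 0)
    released <- lengths(cand) >= min_size | n_chr >= 1
    ord <- order(-lengths(cand), vapply(cand, min, ""))
    cand <- cand[ord]; n_chr <- n_chr[ord]; released <- released[ord]
    status <- ifelse(released, "released", "withheld")
    sf_id <- character(length(cand))
    sf_id[released] <- sprintf("SF%02d", seq_len(sum(released)))
    sf_id[!released] <- sprintf("WH%02d", seq_len(sum(!released)))
  } else {
    n_chr <- numeric(0); status <- character(0); sf_id <- character(0)
  }
  modal <- vapply(seq_along(cand), function(k) {
    acts <- records$activity[match(cand[[k]], records$id)]
    acts <- acts[chr[cand[[k]]] & !is.na(acts)]
    if (!length(acts)) NA_character_ else names(sort(table(acts), decreasing = TRUE))[1]
  }, "")
  subfam <- data.frame(subfamily_id = sf_id, status = status,
                       n_representatives = as.integer(lengths(cand)),
                       n_full = as.integer(lengths(cand)),
                       n_characterized = as.integer(n_chr),
                       modal_activity = modal, stringsAsFactors = FALSE)
  membership <- data.frame(
    member_id = c(unlist(cand, use.names = FALSE), singletons),
    representative_id = c(unlist(cand, use.names = FALSE), singletons),
    subfamily_id = c(rep(sf_id, lengths(cand)), rep(NA_character_, length(singletons))),
    status = c(rep(status, lengths(cand)), rep("singleton", length(singletons))),
    stringsAsFactors = FALSE)
  structure(list(threshold_exponent = igraph::graph_attr(graph, "threshold_exponent"),
                 subfamilies = subfam, membership = membership,
                 non_subclassified = sort(singletons), expanded = FALSE),
            class = "subfamily_partition")
}

#' @export
print.subfamily_partition <- function(x, ...) {
  n_rel <- sum(x$subfamilies$status == "released")
  cat(sprintf("subfamily partition at 1e-%s: %d released, %d withheld, %d singleton(s)%s\n",
              x$threshold_exponent %||% "?", n_rel,
              sum(x$subfamilies$status == "withheld"),
              length(x$non_subclassified),
              if (x$expanded) " [expanded to full membership]" else ""))
  invisible(x)
}

#' Expand a representative-level partition to full family membership
#'
#' Members removed by the redundancy filter inherit the subfamily and status
#' of their cluster representative, recovering per-subfamily counts over the
#' whole (pre-filter) family.
#'
#' @param partition a `subfamily_partition` whose members are cluster
#'   representatives.
#' @param clustering the [cluster_redundancy()] result used upstream; every
#'   partition member must appear among its representatives.
#' @return the partition with `membership` expanded and `n_full` updated.
#' @export
expand_to_full <- function(partition, clustering) {
  reps <- partition$membership$representative_id
  miss <- setdiff(reps, clustering$representatives)
  if (length(miss))
    stopf("representative(s) missing from clustering: %s",
          paste(utils::head(miss, 5), collapse = ", "))
  sizes <- lengths(clustering$clusters)[reps]
  full <- data.frame(
    member_id = unlist(clustering$clusters[reps], use.names = FALSE),
    representative_id = rep(reps, sizes),
    subfamily_id = rep(partition$membership$subfamily_id, sizes),
    status = rep(partition$membership$status, sizes),
    stringsAsFactors = FALSE)
  tab <- table(factor(full$subfamily_id, levels = partition$subfamilies$subfamily_id))
  partition$subfamilies$n_full <- as.integer(tab)
  partition$membership <- full
  partition$expanded <- TRUE
  partition
}

#' Track component splits across thresholds (split tree)
#'
#' Computes the connected components at each listed exponent (coarse to
#' fine) and links every finer component to the unique coarser component
#' containing it — edge nesting across thresholds guarantees uniqueness.
#' This is the containment forest underlying subfamily-emergence diagrams.
#'
#' @param hits hit table data.frame.
#' @param exponents strictly increasing integer exponents (>= 2 of them);
#'   typically the detected peaks plus the selected threshold.
#' @param node_ids optional fixed node set.
#' @param records optional records for per-component characterized-activity
#'   tallies.
#' @param edge_rule see [build_ssn()].
#' @return an object of class `split_tree`: list with `nodes` (data.frame:
#'   `node_id`, `exponent`, `size`, `n_characterized`, `activities`),
#'   `edges` (data.frame: `parent`, `child`), `members` (named list of
#'   member ids per node).
#' @export
build_split_tree <- function(hits, exponents, node_ids = NULL, records = NULL,
                             edge_rule = c("le", "lt")) {
  edge_rule <- match.arg(edge_rule)
  if (length(exponents) < 2 || any(diff(exponents) <= 0))
    stopf("need >= 2 strictly increasing exponents")
  if (is.null(node_ids))
    node_ids <- sort(unique(c(hits$query_id, hits$subject_id)))
  chr_act <- NULL
  if (!is.null(records)) {
    is_chr <- records$characterized %||% rep(FALSE, nrow(records))
    chr_act <- setNames(ifelse(!is.na(is_chr) & is_chr,
                               records$activity, NA_character_), records$id)
  }
  nodes <- list(); edges <- list(); members <- list()
  prev_ids <- NULL; prev_membership <- NULL
  for (e in exponents) {
    g <- build_ssn(hits, e, node_ids = node_ids, edge_rule = edge_rule)
    comp <- igraph::components(g)
    grp <- split(igraph::V(g)$name, comp$membership)
    grp <- grp[order(-lengths(grp), vapply(grp, min, ""))]
    ids <- sprintf("e%d_c%02d", e, seq_along(grp))
    for (k in seq_along(grp)) {
      mem <- grp[[k]]
      acts <- if (is.null(chr_act)) character(0) else
        sort(unique(chr_act[mem][!is.na(chr_act[mem])]))
      nodes[[ids[k]]] <- data.frame(
        node_id = ids[k], exponent = e, size = length(mem),
        n_characterized = if (is.null(chr_act)) NA_integer_
                          else sum(!is.na(chr_act[mem])),
        activities = paste(acts, collapse = "+"), stringsAsFactors = FALSE)
      members[[ids[k]]] <- mem
      if (!is.null(prev_membership)) {
        parent <- unique(prev_membership[mem])
        if (length(parent) != 1)
          stopf("component %s is not nested within a single coarser component", ids[k])
        edges[[length(edges) + 1L]] <- data.frame(parent = parent, child = ids[k],
                                                  stringsAsFactors = FALSE)
      }
    }
    prev_membership <- setNames(rep(ids, lengths(grp)), unlist(grp, use.names = FALSE))
  }
  structure(list(nodes = do.call(rbind, c(nodes, list(make.row.names = FALSE))),
                 edges = if (length(edges)) do.call(rbind, edges)
                         else data.frame(parent = character(), child = character()),
                 members = members),
            class = "split_tree")
}

#' @export
print.split_tree <- function(x, ...) {
  cat(sprintf("split tree: %d components over exponents %s\n",
              nrow(x$nodes), paste(unique(x$nodes$exponent), collapse = ", ")))
  invisible(x)
}

#' Serialize a split tree to nested JSON
#' @param tree a `split_tree`.
#' @param path output path.
#' @export
write_split_tree_json <- function(tree, path) {
  kids <- split(tree$edges$child, tree$edges$parent)
  as_nested <- function(id) {
    row <- tree$nodes[tree$nodes$node_id == id, ]
    out <- list(node_id = id, exponent = row$exponent, size = row$size)
    if (!is.na(row$n_characterized)) {
      out$n_characterized <- row$n_characterized
      if (nzchar(row$activities)) out$activities <- row$activities
    }
    ch <- kids[[id]]
    if (!is.null(ch)) out$children <- lapply(ch, as_nested)
    out
  }
  roots <- setdiff(tree$nodes$node_id, tree$edges$child)
  jsonlite::write_json(lapply(roots, as_nested), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a split tree to Graphviz DOT
#' @param tree a `split_tree`.
#' @param path output path.
#' @export
write_split_tree_dot <- function(tree, path) {
  lab <- sprintf("  \"%s\" [label=\"%s\\nn=%d\"];",
                 tree$nodes$node_id, tree$nodes$node_id, tree$nodes$size)
  edg <- sprintf("  \"%s\" -> \"%s\";", tree$edges$parent, tree$edges$child)
  writeLines(c("digraph split_tree {", lab, edg, "}"), path)
  invisible(path)
}

#' Functional homogeneity of subfamilies
#'
#' For each candidate subfamily, tallies the activities of its characterized
#' members: `purity` is the share of the modal activity among characterized
#' members (ties broken lexicographically), and is `NA` when a subfamily has
#' no characterized member.
#'
#' @param partition a `subfamily_partition`.
#' @param records records with `characterized` and `activity`.
#' @return data.frame: `subfamily_id`, `status`, `n_characterized`,
#'   `modal_activity`, `purity`.
#' @export
functional_homogeneity <- function(partition, records) {
  mem <- partition$membership
  mem <- mem[!is.na(mem$subfamily_id), , drop = FALSE]
  acts <- records$activity[match(mem$member_id, records$id)]
  chr <- records$characterized[match(mem$member_id, records$id)]
  keep <- !is.na(chr) & chr & !is.na(acts)
  out <- partition$subfamilies[, c("subfamily_id", "status")]
  out$n_characterized <- 0L
  out$modal_activity <- NA_character_
  out$purity <- NA_real_
  tal <- split(acts[keep], mem$subfamily_id[keep])
  for (sf in names(tal)) {
    tb <- sort(table(tal[[sf]]), decreasing = TRUE)
    k <- match(sf, out$subfamily_id)
    out$n_characterized[k] <- length(tal[[sf]])
    out$modal_activity[k] <- names(tb)[1]
    out$purity[k] <- as.integer(tb[1]) / length(tal[[sf]])
  }
  out
}

#' Secretion-signal percentages per subfamily and taxon group
#'
#' Members with a predicted transmembrane segment are filtered out first;
#' within each (subfamily, taxon group) cell the percentage of remaining
#' members with a predicted signal peptide is reported. Cells left empty
#' after the transmembrane filter get `NA`.
#'
#' @param partition a `subfamily_partition`.
#' @param records records with `taxon`, `sp_flag`, `tm_flag`.
#' @param taxon_grouping optional two-column data.frame (`taxon`, `group`)
#'   collapsing taxa into groups; default is pass-through.
#' @return data.frame: `subfamily_id`, `taxon_group`, `n_considered`,
#'   `n_secreted`, `percent_secreted`.
#' @export
secretion_summary <- function(partition, records, taxon_grouping = NULL) {
  mem <- partition$membership
  mem <- mem[!is.na(mem$subfamily_id), , drop = FALSE]
  k <- match(mem$member_id, records$id)
  df <- data.frame(subfamily_id = mem$subfamily_id,
                   taxon = records$taxon[k],
                   sp = records$sp_flag[k], tm = records$tm_flag[k],
                   stringsAsFactors = FALSE)
  if (!is.null(taxon_grouping)) {
    g <- taxon_grouping$group[match(df$taxon, taxon_grouping$taxon)]
    df$taxon <- ifelse(is.na(g), df$taxon, g)
  }
  cells <- split(df, list(df$subfamily_id, df$taxon), drop = TRUE)
  out <- do.call(rbind, lapply(cells, function(cell) {
    kept <- cell[is.na(cell$tm) | !cell$tm, , drop = FALSE]
    kept <- kept[!is.na(kept$sp), , drop = FALSE]
    data.frame(subfamily_id = cell$subfamily_id[1], taxon_group = cell$taxon[1],
               n_considered = nrow(kept), n_secreted = sum(kept$sp),
               percent_secreted = if (nrow(kept)) 100 * sum(kept$sp) / nrow(kept)
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$subfamily_id, out$taxon_group), , drop = FALSE]
}
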