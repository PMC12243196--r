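# Brute-force oracles, deliberately independent of the package's compiled
# aligners and of igraph: alignments are enumerated over all
# order-preserving pairings of residue positions, and graph distances come
# from a hand-written BFS.

# Global-alignment identity under match = 1 / mismatch = 0 / linear gap cost:
# enumerate every set of aligned position pairs (strictly increasing in both
# sequences); unaligned residues are gaps. Among score-optimal alignments
# report the maximal match count, over the shorter length.
oracle_global_identity <- function(a, b, gap_cost = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best_score <- -Inf; best_matches <- -1L
  for (k in 0:min(la, lb)) {
    ia_set <- if (k == 0) list(integer(0)) else asplit(combn(la, k), 2)
    ib_set <- if (k == 0) list(integer(0)) else asplit(combn(lb, k), 2)
    for (ia in ia_set) for (ib in ib_set) {
      m <- sum(av[ia] == bv[ib])
      score <- m - gap_cost * ((la - k) + (lb - k))
      if (score > best_score || (score == best_score && m > best_matches)) {
        best_score <- score; best_matches <- m
      }
    }
  }
  best_matches / min(la, lb)
}

# Local alignment with affine gaps: same enumeration, no end-gap costs, and
# each internal gap of length g costs gap_open + g * gap_extend. The empty
# alignment scores 0.
oracle_sw_score <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  best <- 0
  for (k in seq_len(min(la, lb))) {
    for (ia in asplit(combn(la, k), 2)) for (ib in asplit(combn(lb, k), 2)) {
      s <- sum(submat[cbind(av[ia], bv[ib])])
      if (k > 1) {
        ga <- diff(ia) - 1L; gb <- diff(ib) - 1L
        s <- s - sum((gap_open + gap_extend * ga)[ga > 0]) -
          sum((gap_open + gap_extend * gb)[gb > 0])
      }
      if (s > best) best <- s
    }
  }
  best
}

# Per-node closeness by hand-rolled BFS over an edge list.
oracle_closeness <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (r in seq_len(nrow(edges))) {
    u <- edges$from[r]; v <- edges$to[r]
    if (u == v) next
    adj[[u]] <- union(adj[[u]], v)
    adj[[v]] <- union(adj[[v]], u)
  }
  out <- setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[v] <- 0
    frontier <- v
    while (length(frontier)) {
      nxt <- character(0)
      for (u in frontier) for (w in adj[[u]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[u] + 1; nxt <- c(nxt, w) }
      }
      frontier <- unique(nxt)
    }
    reach <- dist[is.finite(dist) & names(dist) != v]
    out[v] <- if (length(reach)) length(reach) / sum(reach) else 0
  }
  out
}

oracle_weighted_avg_closeness <- function(nodes, edges)
  mean(oracle_closeness(nodes, edges))

# Erdos-Renyi helper for oracle comparisons.
random_edges <- function(n, p, seed) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(combn(n, 2))
  set.seed(seed)
  keep <- runif(nrow(pairs)) < p
  list(nodes = nodes,
       edges = data.frame(from = nodes[pairs[keep, 1]],
                          to = nodes[pairs[keep, 2]],
                          stringsAsFactors = FALSE))
}

# Minimal hit table carrying only what SSN construction consumes.
hits_from_edges <- function(edges, evalue) {
  data.frame(query_id = edges$from, subject_id = edges$to,
             evalue = rep_len(evalue, nrow(edges)), stringsAsFactors = FALSE)
}

graph_from_edges <- function(edges, nodes, exponent = 10) {
  build_ssn(hits_from_edges(edges, 1e-300), exponent, node_ids = nodes)
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, replace = TRUE),
        collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
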