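# build a partition from explicit component blocks: each element of `blocks`
# is a vector of member ids forming one clique; extra ids become singletons
partition_from_blocks <- function(blocks, characterized = character(0),
                                  singletons = character(0), min_size = 30,
                                  activities = NULL) {
  edges <- do.call(rbind, lapply(blocks, function(v) {
    d <- as.data.frame(t(combn(v, 2)), stringsAsFactors = FALSE)
    names(d) <- c("from", "to"); d
  }))
  ids <- c(unlist(blocks), singletons)
  g <- graph_from_edges(edges, ids)
  rec <- data.frame(id = ids, sequence = "M", coverage = 1,
                    characterized = ids %in% characterized,
                    activity = if (is.null(activities)) NA_character_
                               else activities[ids],
                    stringsAsFactors = FALSE)
  partition_at_threshold(g, rec, min_size = min_size)
}

test_that("release rules reproduce the characterized-member and size criteria", {
  mk <- function(n, pre) sprintf("%s%03d", pre, seq_len(n))
  # 22-member component with one characterized member: released
  p <- partition_from_blocks(list(mk(22, "a")), characterized = "a001")
  expect_identical(p$subfamilies$status, "released")
  # uncharacterized components of 17..26 members: withheld
  p2 <- partition_from_blocks(list(mk(17, "b"), mk(22, "c"), mk(26, "d")))
  expect_identical(p2$subfamilies$status, rep("withheld", 3))
  # exactly 30 uncharacterized members: released at the boundary
  p3 <- partition_from_blocks(list(mk(30, "e")))
  expect_identical(p3$subfamilies$status, "released")
  expect_identical(p3$subfamilies$n_representatives, 30L)
})

test_that("stable ids are assigned by decreasing size with smallest-member tie-break", {
  mk <- function(n, pre) sprintf("%s%03d", pre, seq_len(n))
  p <- partition_from_blocks(list(mk(31, "z"), mk(40, "m"), mk(31, "a")),
                             singletons = c("q1", "q2"))
  sf <- p$subfamilies
  expect_identical(sf$subfamily_id, c("SF01", "SF02", "SF03"))
  expect_identical(sf$n_representatives, c(40L, 31L, 31L))
  # the two 31-member groups: the one containing "a001" sorts first
  mem <- p$membership[!is.na(p$membership$subfamily_id), ]
  expect_true(all(startsWith(mem$member_id[mem$subfamily_id == "SF02"], "a")))
  expect_setequal(p$non_subclassified, c("q1", "q2"))
})

test_that("representatives are covered exactly once across released, withheld, singleton", {
  mk <- function(n, pre) sprintf("%s%03d", pre, seq_len(n))
  p <- partition_from_blocks(list(mk(35, "a"), mk(10, "b")),
                             singletons = c("s1", "s2", "s3"))
  mem <- p$membership
  expect_identical(anyDuplicated(mem$member_id), 0L)
  expect_identical(nrow(mem), 48L)
  expect_identical(sort(table(mem$status), decreasing = TRUE),
                   sort(table(c(rep("released", 35), rep("withheld", 10),
                                rep("singleton", 3))), decreasing = TRUE))
})

test_that("expansion propagates subfamily labels through redundancy clusters", {
  mk <- function(n, pre) sprintf("%s%03d", pre, seq_len(n))
  p <- partition_from_blocks(list(mk(30, "a")), singletons = "s1")
  # identity expansion: singleton clusters only
  cl1 <- structure(list(clusters = as.list(setNames(nm = p$membership$member_id)),
                        representatives = p$membership$member_id,
                        identity_threshold = 0.8),
                   class = "redundancy_clustering")
  e1 <- expand_to_full(p, cl1)
  expect_identical(e1$subfamilies$n_full, e1$subfamilies$n_representatives)
  # one representative with 4 redundant members
  cl2 <- cl1
  cl2$clusters[["a001"]] <- c("a001", sprintf("x%02d", 1:4))
  e2 <- expand_to_full(p, cl2)
  expect_identical(e2$subfamilies$n_full, 34L)
  expect_identical(sum(e2$membership$status == "released"), 34L)
  # missing representative is reported by name
  cl3 <- cl1
  cl3$clusters[["a001"]] <- NULL
  cl3$representatives <- setdiff(cl3$representatives, "a001")
  expect_error(expand_to_full(p, cl3), "a001")
})

test_that("expanded fractions match brute-force label propagation", {
  fam <- simulate_family(family_sim_config(5, rep(24, 5), seq_length = 60,
                                           within_divergence = 0.03,
                                           between_divergence = 0.55, seed = 20))
  cl <- cluster_redundancy(fam$records, 0.8)
  reps <- fam$records[match(cl$representatives, fam$records$id), ]
  hits <- simulate_hit_table(fam$truth[match(reps$id, fam$truth$id), ],
                             list(same_subfamily = c(-80, -70),
                                  different = c(-28.5, -18.5)), seed = 21)
  g <- build_ssn(hits, 50, node_ids = reps$id)
  p <- expand_to_full(partition_at_threshold(g, reps, min_size = 2), cl)
  # oracle: propagate each representative's label to its cluster by hand
  lab <- setNames(p$membership$subfamily_id[match(cl$representatives,
                                                  p$membership$representative_id)],
                  cl$representatives)
  manual <- unlist(lapply(cl$representatives, function(r)
    setNames(rep(lab[[r]], length(cl$clusters[[r]])), cl$clusters[[r]])))
  got <- setNames(p$membership$subfamily_id, p$membership$member_id)
  expect_identical(got[names(manual)], manual)
  frac <- sum(p$subfamilies$n_full[p$subfamilies$status == "released"]) / nrow(fam$records)
  expect_equal(frac, mean(!is.na(manual[fam$records$id])))
})

test_that("split tree is a chain for one persistent clique", {
  clique <- as.data.frame(t(combn(sprintf("n%d", 1:6), 2)), stringsAsFactors = FALSE)
  names(clique) <- c("from", "to")
  tree <- build_split_tree(hits_from_edges(clique, 1e-120), c(25, 40, 59))
  expect_identical(nrow(tree$nodes), 3L)
  expect_identical(nrow(tree$edges), 2L)
  expect_true(all(tree$nodes$size == 6L))
})

test_that("split tree recovers a planted two-level hierarchy", {
  cfg <- family_sim_config(4, rep(10, 4), seq_length = 50, seed = 22,
                           hierarchy = list(groups = list(1:2, 3:4),
                                            divergence = 0.4))
  fam <- simulate_family(cfg)
  hits <- simulate_hit_table(fam$truth,
                             list(same_subfamily = c(-90, -80),
                                  same_supergroup = c(-60.5, -50.5),
                                  different = c(-28.5, -18.5)), seed = 23)
  tree <- build_split_tree(hits, c(40, 70), records = fam$records)
  lvl1 <- tree$nodes[tree$nodes$exponent == 40, ]
  lvl2 <- tree$nodes[tree$nodes$exponent == 70, ]
  expect_identical(nrow(lvl1), 2L)
  expect_identical(nrow(lvl2), 4L)
  expect_true(all(table(tree$edges$parent) == 2))
  # child member sets partition each parent
  for (par in lvl1$node_id) {
    kids <- tree$edges$child[tree$edges$parent == par]
    expect_setequal(unlist(tree$members[kids]), tree$members[[par]])
  }
  # sizes along any root-to-leaf path are non-increasing
  sizes <- setNames(tree$nodes$size, tree$nodes$node_id)
  expect_true(all(sizes[tree$edges$child] <= sizes[tree$edges$parent]))
})

test_that("split tree serializes to JSON and DOT", {
  clique <- as.data.frame(t(combn(c("a", "b", "c"), 2)), stringsAsFactors = FALSE)
  names(clique) <- c("from", "to")
  tree <- build_split_tree(hits_from_edges(clique, 1e-120), c(25, 40))
  jp <- withr::local_tempfile(fileext = ".json")
  dp <- withr::local_tempfile(fileext = ".dot")
  write_split_tree_json(tree, jp)
  parsed <- jsonlite::read_json(jp)
  expect_length(parsed, 1L)
  expect_identical(parsed[[1]]$size, 3L)
  write_split_tree_dot(tree, dp)
  expect_true(any(grepl("->", readLines(dp))))
})

test_that("functional homogeneity tallies modal activity and purity", {
  mk <- function(n, pre) sprintf("%s%03d", pre, seq_len(n))
  ids <- mk(8, "a")
  acts <- setNames(c("bGal", "bGal", "bGal", "bGalA", rep(NA, 4)), ids)
  p <- partition_from_blocks(list(ids), characterized = ids[1:4],
                             activities = acts, min_size = 2)
  hom <- functional_homogeneity(p, data.frame(
    id = ids, sequence = "M", characterized = ids %in% ids[1:4],
    activity = unname(acts), stringsAsFactors = FALSE))
  expect_identical(hom$modal_activity, "bGal")
  expect_equal(hom$purity, 0.75)
  # all one activity -> purity 1; none characterized -> NA
  p2 <- partition_from_blocks(list(mk(4, "b"), mk(4, "c")),
                              characterized = mk(4, "b"), min_size = 2,
                              activities = setNames(rep("bGlcA", 8),
                                                    c(mk(4, "b"), mk(4, "c"))))
  hom2 <- functional_homogeneity(p2, data.frame(
    id = c(mk(4, "b"), mk(4, "c")), sequence = "M",
    characterized = c(rep(TRUE, 4), rep(FALSE, 4)),
    activity = "bGlcA", stringsAsFactors = FALSE))
  expect_equal(hom2$purity[hom2$n_characterized > 0], 1)
  expect_true(is.na(hom2$purity[hom2$n_characterized == 0]))
})

test_that("per-subfamily purity equals a brute-force tally on planted labels", {
  fam <- simulate_family(family_sim_config(4, rep(15, 4), seq_length = 40,
                                           frac_characterized = 0.4, seed = 24))
  hits <- simulate_hit_table(fam$truth,
                             list(same_subfamily = c(-80, -70),
                                  different = c(-28.5, -18.5)), seed = 25)
  g <- build_ssn(hits, 50, node_ids = fam$truth$id)
  p <- partition_at_threshold(g, fam$records, min_size = 2)
  hom <- functional_homogeneity(p, fam$records)
  for (k in seq_len(nrow(hom))) {
    members <- p$membership$member_id[p$membership$subfamily_id == hom$subfamily_id[k]]
    rec <- fam$records[fam$records$id %in% members, ]
    acts <- rec$activity[rec$characterized & !is.na(rec$activity)]
    expect_identical(hom$n_characterized[k], length(acts))
    if (length(acts))
      expect_equal(hom$purity[k], max(table(acts)) / length(acts))
  }
})

test_that("secretion summary excludes TM proteins and tallies percentages", {
  ids <- sprintf("a%02d", 1:4)
  p <- partition_from_blocks(list(ids), min_size = 2)
  rec <- data.frame(id = ids, sequence = "M", taxon = "Bacteria",
                    sp_flag = c(TRUE, TRUE, TRUE, FALSE),
                    tm_flag = c(FALSE, FALSE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  s <- secretion_summary(p, rec)
  expect_identical(s$n_considered, 3L)
  expect_identical(s$n_secreted, 2L)
  expect_equal(s$percent_secreted, 100 * 2 / 3, tolerance = 1e-12)
  rec$sp_flag <- TRUE; rec$tm_flag <- FALSE
  expect_equal(secretion_summary(p, rec)$percent_secreted, 100)
})

test_that("secretion percentages per cell equal a brute-force tally", {
  fam <- simulate_family(family_sim_config(3, rep(20, 3), seq_length = 40,
                                           seed = 26, sp_prob = 0.6, tm_prob = 0.2))
  hits <- simulate_hit_table(fam$truth,
                             list(same_subfamily = c(-80, -70),
                                  different = c(-28.5, -18.5)), seed = 27)
  g <- build_ssn(hits, 50, node_ids = fam$truth$id)
  p <- partition_at_threshold(g, fam$records, min_size = 2)
  s <- secretion_summary(p, fam$records)
  for (k in seq_len(nrow(s))) {
    members <- p$membership$member_id[p$membership$subfamily_id == s$subfamily_id[k]]
    rec <- fam$records[fam$records$id %in% members &
                         fam$records$taxon == s$taxon_group[k], ]
    rec <- rec[!rec$tm_flag, ]
    expect_identical(s$n_considered[k], nrow(rec))
    if (nrow(rec))
      expect_equal(s$percent_secreted[k], 100 * mean(rec$sp_flag))
  }
})

test_that("the pipeline recovers a planted family and is deterministic", {
  fam <- simulate_family(family_sim_config(5, c(32, 34, 36, 38, 40),
                                           seq_length = 240, seed = 30))
  hits <- simulate_hit_table(fam$truth,
                             list(same_subfamily = c(-80, -70),
                                  different = c(-28.5, -18.5)), seed = 31)
  config <- list(records = fam$records, hits = hits, kmer_screen = TRUE)
  res <- run_pipeline(config, verbose = FALSE)
  expect_gt(res$selected_exponent, 28.5)
  expect_lt(res$selected_exponent, 70)
  mem <- res$partition$membership
  lab <- setNames(mem$subfamily_id, mem$member_id)
  ari <- mclust::adjustedRandIndex(lab[fam$truth$id], fam$truth$subfamily)
  expect_equal(ari, 1.0)
  expect_identical(sum(res$partition$subfamilies$status == "released"), 5L)
  res2 <- run_pipeline(config, verbose = FALSE)
  expect_identical(res$counts, res2$counts)
  expect_identical(res$partition, res2$partition)
})

test_that("pipeline errors name the failing stage", {
  expect_error(run_pipeline(list(records = data.frame()), verbose = FALSE),
               "seq_prep")
  bad <- list(records = data.frame(id = "a", sequence = "M", coverage = 1,
                                   stringsAsFactors = FALSE),
              hits = data.frame(bogus = 1))
  expect_error(run_pipeline(bad, verbose = FALSE), "similarity")
})
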