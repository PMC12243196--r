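#!/usr/bin/env Rscript

# Stage 1: simulate the study family.
#
# We emulate a large glycoside-hydrolase-like protein family whose subfamily
# structure is known by construction: 7 subfamilies nested in 3 supergroups,
# with three well-separated log10 E-value bands (within-subfamily,
# within-supergroup, between-supergroup), a minority of "characterized"
# members carrying activity labels, round-robin taxa, and per-protein
# secretion/transmembrane flags. A handful of exact duplicates and
# low-coverage fragments are added so the preparation stages have real work
# to do.

suppressPackageStartupMessages(library(ssnsubfam))
dir.create("results", showWarnings = FALSE)

cfg <- family_sim_config(
  n_subfamilies = 7,
  subfamily_sizes = c(60, 48, 44, 40, 36, 34, 32),
  hierarchy = list(groups = list(1:3, 4:5, 6:7), divergence = 0.4),
  frac_characterized = 0.1,
  taxa = c("Bacteria", "Eukaryota", "Archaea"),
  seed = 20230701)
fam <- simulate_family(cfg)

# Within-subfamily pairs align far better than anything else; supergroup-level
# similarity spans a broad band across most of the sweep, so supergroup
# components thin out gradually (never forming cliques) and the family fully
# resolves only near the stringent end — the regime in which closeness
# centrality is informative.
bands <- list(same_subfamily = c(-90, -80),
              same_supergroup = c(-58.5, -20.5),
              different = c(-28.5, -18.5))

# plant redundancy: exact duplicates of every 10th sequence
dup_src <- fam$records[seq(1, nrow(fam$records), by = 10), ]
dups <- transform(dup_src, id = sub("seq", "dup", id),
                  characterized = FALSE, activity = NA_character_)
records <- rbind(fam$records, dups)

# the all-vs-all table covers duplicates too (they may end up representing
# their cluster), with the planted relation of their source sequence
truth_ext <- rbind(fam$truth,
                   transform(fam$truth[seq(1, nrow(fam$truth), by = 10), ],
                             id = sub("seq", "dup", id)))
attr(truth_ext, "seq_length") <- cfg$seq_length
hits <- simulate_hit_table(truth_ext, bands, seed = 20230702)

# plant fragments: ~5% of sequences get sub-threshold profile coverage
set.seed(20230703)
frag <- sample(nrow(records), round(0.05 * nrow(records)))
records$coverage[frag] <- runif(length(frag), 0.25, 0.45)

write_family(records, "results/family.fasta", "results/family_meta.tsv",
             truth = fam$truth)
write_hits_tabular(hits, "results/family_hits.tsv")

message(sprintf("Simulated %d sequences (%d planted subfamilies in %d supergroups),",
                nrow(records), cfg$n_subfamilies, length(cfg$hierarchy$groups)))
message(sprintf("  %d characterized members, %d exact duplicates, %d low-coverage fragments.",
                sum(records$characterized), nrow(dups), length(frag)))
message(sprintf("  %d directed hits in three log10-E bands -> results/family_hits.tsv",
                nrow(hits)))
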