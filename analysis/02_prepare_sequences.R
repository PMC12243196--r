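#!/usr/bin/env Rscript

# Stage 2: sequence preparation.
#
# Mirrors the family curation applied before any network is built: domain
# sequences must cover at least half of the family profile HMM, and
# near-identical sequences are collapsed at 80% identity by greedy
# longest-first clustering so that dense clades do not distort the network's
# centrality.

suppressPackageStartupMessages(library(ssnsubfam))

records <- read_family("results/family.fasta", "results/family_meta.tsv")
message(sprintf("Loaded %d sequences.", nrow(records)))

kept <- filter_by_coverage(records, min_cov = 0.5)
message(sprintf("Coverage filter (>= 0.5): kept %d, removed %d fragments.",
                nrow(kept), nrow(records) - nrow(kept)))

clustering <- cluster_redundancy(kept, identity_threshold = 0.8,
                                 kmer_screen = TRUE)
write_clustering_tsv(clustering, "results/redundancy_clusters.tsv")
reps <- kept[match(clustering$representatives, kept$id), ]
write_family(reps, "results/representatives.fasta")

n_collapsed <- nrow(kept) - length(clustering$clusters)
message(sprintf("Redundancy filter (80%% identity): %d representatives, %d members collapsed.",
                length(clustering$clusters), n_collapsed))
message("Wrote results/redundancy_clusters.tsv and results/representatives.fasta")
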