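#!/usr/bin/env Rscript

# Linear clustering of CerTra cohort missense variants along CERT.
#
# The cohort panel lists the variant positions named in the study (clusters
# 1-4 in the inter-domain region plus the non-clustered variants); the
# transcript model is CERT isoform 1 (624 aa) with its PH, SRR, FFAT and
# START annotations. We test whether variants sit closer together along the
# protein than uniformly placed ones, globally and within each predefined
# spatial group.

library(certra)

seed <- 20230328L
n_perm <- 1e6
dir.create("results", showWarnings = FALSE)

tm <- read_transcript_model(system.file("extdata", "certra_transcript.tsv",
                                        package = "certra"))
panel <- read_variant_table(system.file("extdata",
                                        "certra_cohort_variants.tsv",
                                        package = "certra"), tm)
print(tm)
print(panel)

glob <- permutation_test(panel, n_perm = n_perm, seed = seed)
cat("\nGlobal test (distinct positions vs uniform placement):\n")
print(glob)

cl <- read.delim(system.file("extdata", "certra_clusters.tsv",
                             package = "certra"))
clusters <- cluster_definitions(cl$name, cl$start, cl$end, tm)
res <- cluster_delta_g(panel, clusters, n_perm = n_perm, seed = seed)
cat("\nPer-cluster tests (null: same number of positions anywhere on the",
    "transcript):\n")
for (r in res) print(r)

tab <- rbind(cluster_results_table(glob), cluster_results_table(res))
write.table(tab, "results/01_clustering.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWrote results/01_clustering.tsv\n")
cat("Cluster 2 holds a single recurrent position (T166) and is therefore",
    "reported untestable:\nrecurrence across subjects, not linear spread,",
    "is its signal.\n")
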