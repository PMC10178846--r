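#!/usr/bin/env Rscript

# In-silico pathogenicity classification and cohort comparison.
#
# The study compares CADD/REVEL/M-CAP/Eigen scores of patient variants
# against gnomAD singleton missense variants. Raw per-variant scores are not
# published as machine-readable tables, so this driver demonstrates the
# classification rules on threshold-spanning examples and runs the cohort
# comparison on synthetic score tables with a 1-SD pathogenic shift
# (20 patient vs 200 background variants).

library(certra)

seed <- 7041L
dir.create("results", showWarnings = FALSE)

cat("Threshold policy (pathogenic iff strictly over the cutoff):\n")
str(unclass(score_thresholds()))

demo <- data.frame(
  variant_id = c("all_pathogenic", "boundary_benign", "mixed"),
  cadd = c(25, 20, 30), revel = c(0.6, 0.5, NA),
  mcap = c(0.03, 0.025, 0.01), eigen = c(0.7, 0.5, NA))
cls <- classify_score_table(demo)
print(cls)
write.table(cls, "results/02_classification_demo.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sim <- simulate_score_table(n_pathogenic = 20, n_background = 200,
                            effect_sd = 1, seed = seed)
cmp <- compare_cohorts(sim$patient, sim$background)
cat("\nOne-sided Mann-Whitney U (patient > background), synthetic cohorts:\n")
print(cmp, digits = 4)
write.table(cmp, "results/02_cohort_comparison.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# how often does a 1-SD shift reach the study's P < 0.001 at these sizes?
rej <- vapply(1:200, function(i) {
  s <- simulate_score_table(n_pathogenic = 20, n_background = 200,
                            effect_sd = 1, seed = seed + i)
  mean(compare_cohorts(s$patient, s$background)$p_value < 0.001)
}, numeric(1))
cat(sprintf("\nPer-tool rejection rate at alpha = 0.001 over 200 simulated
cohorts (1 SD shift, n = 20 vs 200): %.2f\n", mean(rej)))
cat("Wrote results/02_classification_demo.tsv,",
    "results/02_cohort_comparison.tsv\n")
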