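# certra

Analyses for **CerTra syndrome**, the neurodevelopmental disorder caused by
dominant missense variants in *CERT1* (the ceramide transporter CERT), as a
tested R package plus numbered analysis drivers. It is aimed at
statistical-genetics and lipid-biology readers who want to re-run, probe or
reuse the study's computational components:

* **Linear variant clustering** — the geometric-mean-distance statistic
  over variant positions $x_1,\dots,x_k$ on a protein of length $L$,
  $\delta_g = \big(\prod_{i<j}|x_i-x_j|/L\big)^{1/\binom{k}{2}}$, with a
  seeded permutation test (null: $k$ distinct uniform positions,
  one-sided empirical $p = (n_\le+1)/(n_{perm}+1)$) and an exhaustive
  enumeration oracle for small instances.
* **Pathogenicity scores** — CADD/REVEL/M-CAP/Eigen threshold
  classification (pathogenic strictly over 20 / 0.5 / 0.025 / 0.5) with a
  consensus rule, and patient-vs-background cohort comparison via a
  from-scratch Mann–Whitney U test (exact enumeration or tie-corrected
  normal approximation).
* **Stable-isotope sphingolipid flux** — newly synthesized fractions
  $f = \mathrm{SO{+}3}/(\mathrm{SO}+\mathrm{SO{+}3})$ (and the sphinganine
  analogue), percent changes vs a reference condition, per-channel one-way
  ANOVA, species-to-class aggregation with exact conservation.
* **Oligomer stoichiometry** — theoretical protein masses from the average
  residue-mass table and integer stoichiometry calls
  $k^\* = \arg\min_k |m - kM|/(kM)$ for native-MS / SEC-MALS peaks.
* **Synthetic-data generators** — seeded, truth-emitting simulators for
  variant panels, score cohorts, labeled lipidomics datasets and mass
  peaks, so every stage is testable without downloads.

## Worked example

```r
library(certra)
tm    <- read_transcript_model(system.file("extdata", "certra_transcript.tsv",
                                           package = "certra"))
panel <- read_variant_table(system.file("extdata", "certra_cohort_variants.tsv",
                                        package = "certra"), tm)
permutation_test(panel, n_perm = 1e6, seed = 20230328)
```

```
[global] delta_g = 0.15888 over 20 positions; p = 0.00671
         (6710 of 1e+06 permutations <= observed; seed 20230328)
```

The cohort's 20 distinct variant positions sit closer together along CERT
than uniformly placed positions would (p ≈ 0.007): variants concentrate in
the region between the PH and START domains. Within the predefined spatial
groups the effect is far stronger — e.g. the four serine-rich-region
positions 132/135/138/141:

```r
cl  <- read.delim(system.file("extdata", "certra_clusters.tsv", package = "certra"))
res <- cluster_delta_g(panel, cluster_definitions(cl$name, cl$start, cl$end, tm),
                       n_perm = 1e6, seed = 20230328)
res$cluster1_SRR
```

```
[cluster1_SRR] delta_g = 0.0072745 over 4 positions; p = 1e-05
               (9 of 1e+06 permutations <= observed; seed 1580635293)
```

i.e. four positions spanning nine residues of a 624-residue protein — about
as tight as 4 random positions land anywhere on the transcript once in
10^5 permutations. And the native-MS side:

```r
annotate_peaks(c(18.5, 37, 71.5), monomer_mw = 18.5)
```

```
  observed_mass k expected_mass relative_error accepted
1          18.5 1          18.5     0.00000000     TRUE
2          37.0 2          37.0     0.00000000     TRUE
3          71.5 4          74.0     0.03378378     TRUE
```

the 37 kDa peak is a dimer of the 18.5 kDa central-core-domain monomer and
71.5 kDa a tetramer (3.4% off four monomers, inside the 5% acceptance
tolerance).

## Analysis drivers

`analysis/01_variant_clustering.R` … `04_mass_stoichiometry.R` are thin
narrative scripts over the package functions; each prints what it found and
writes its tables under `results/`.

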