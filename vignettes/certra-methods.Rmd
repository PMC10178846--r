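---
title: "Methods behind certra: variant clustering, score cohorts, isotope flux and oligomer masses"
author: "certra authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind certra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(certra)
```

CerTra syndrome is a neurodevelopmental disorder caused by dominant
missense variants in *CERT1*, the gene encoding the ceramide transporter
CERT. The gene's variants cluster along the protein, patients' variants
score high on in-silico pathogenicity predictors, gain-of-function mutants
derail de novo sphingolipid synthesis (measurable by stable-isotope
labeling), and the protein's central core domain dimerizes (measurable by
native MS and SEC-MALS). `certra` implements the computational side of each
of those observations as small, seeded, testable components. This vignette
explains the models, the defaults, and the numerical and design choices.

## Linear variant clustering: the geometric-mean-distance statistic

For distinct variant positions $x_1 < \dots < x_k$ on a protein of length
$L$, the statistic is the geometric mean of normalized pairwise distances

$$\delta_g \;=\; \Big(\prod_{i<j} \frac{|x_i - x_j|}{L}\Big)^{1/\binom{k}{2}},$$

small when variants sit close together along the chain. Significance is
assessed against a null that places $k$ distinct positions uniformly
without replacement on $1..L$: with $n_\le$ permutations at or below the
observed statistic, the one-sided empirical p-value is
$p = (n_\le + 1)/(n_{\mathrm{perm}} + 1)$. The +1 pseudocount keeps
$p > 0$; ties count toward rejection ("smaller or equal").

Choices that were genuinely open, and how they were settled:

* **Coordinate system.** All positions are 1-based amino-acid coordinates
  and $L$ is the protein length (624 residues for CERT isoform 1, the
  isoform used for residue numbering throughout). Clustering in
  nucleotide space would only rescale distances — $\delta_g$ is invariant
  under joint integer rescaling of positions and $L$, a property the test
  suite checks — so the amino-acid convention is used everywhere.
* **Recurrent variants.** The default `duplicate_policy = "collapse"`
  computes $\delta_g$ over distinct positions, because a position recurring
  in several subjects carries recurrence information, not spread
  information, and any coincident pair would annihilate a geometric mean.
  `"keep"` is available and indeed returns 0 on coincident positions.
* **Null sampling.** Distinct positions (without replacement), matching the
  collapse policy and avoiding $\delta_g = 0$ degeneracies in the null.
* **Per-cluster tests.** A cluster's observed statistic uses the distinct
  observed positions inside its interval; its null still draws from the
  whole transcript, asking "how surprising is it that this many positions
  are this tight *anywhere*". Clusters with fewer than two observed
  positions are flagged untestable rather than dropped. Per-cluster seeds
  derive deterministically from the master seed and cluster index, so a
  result list reproduces bit-identically from one seed.

Numerics: the statistic is computed and compared in log space
(mean of $\log|x_i-x_j|$; the $1/L$ factor cancels in comparisons), with an
absolute tolerance of $10^{-12}$ on the mean-log scale so that permuted
sets realizing the same distance multiset in a different order still count
as ties. The permutation loop is compiled (Rcpp) and consumes R's RNG, so
`set.seed` governs it; a pure-R reference engine with the same contract is
retained and cross-checked against it. The compiled loop does about
$10^6$ permutations per second per position pair-set, which makes the
study-scale $10^8$ permutations feasible ($\sim$minutes) while the default
is $10^5$.

An exhaustive oracle (`exhaustive_test`) enumerates every $k$-subset of
$1..L$ (guarded at $10^6$ subsets) and anchors the sampled test: on random
small instances the sampled p agrees with the exact p within three binomial
standard errors, and under a uniform null the rejection rate at
$\alpha = 0.05$ across 1,000 simulated panels (with $10^4$ permutations
each — the problem size chosen for the calibration suite) stays inside the
exact binomial 99% band.

## Pathogenicity scores and cohort comparison

Per-tool verdicts use strict "over" cutoffs: M-CAP > 0.025, REVEL > 0.5,
Eigen > 0.5, CADD > 20; scores equal to the cutoff are benign, missing
scores are indeterminate. The consensus formalizes "inconsistent
predictions across algorithms": all present verdicts must agree for a
consistent call; a majority-vote mode is available as an alternative.

The cohort contrast (patients vs background singletons) is a from-scratch
Mann–Whitney U test, one-sided (patient scores greater) by default to match
the directional claim it supports; two-sided is available. Missing scores
are dropped pairwise per tool, because the four predictors have disjoint
coverage in practice; tools left with fewer than two values per cohort are
flagged untested rather than failing the run.

* **Exact path**: enumerates rank labelings over the smaller sample.
  Admissibility requires untied data and $\min(n_1,n_2) \le 12$; `auto`
  additionally requires at most $3\times10^5$ labelings so that the cheap
  path is also a fast one (with, say, $n_1 = 10$ vs $n_2 = 50$ the labeling
  count is astronomically large even though $\min(n_1,n_2)$ is small), and
  an explicit `method = "exact"` refuses beyond $5\times10^6$ labelings.
* **Approximate path**: normal approximation with mid-ranks,
  tie-corrected variance
  $\sigma_U^2 = \frac{n_1 n_2}{12}\big(N+1 - \sum_t (t^3-t)/(N(N-1))\big)$
  and a 0.5 continuity correction. On very small, heavily tied lattices
  (three observations per group) the approximation can be far from the
  exact permutation distribution — the U lattice is too coarse — so the
  suite asserts approximation quality from roughly eight observations per
  group upward, where agreement is within a couple of percent.

## Stable-isotope flux quantities

Heavy-serine labeling shifts newly synthesized long-chain bases by +3 mass
units: sphingosine (SO) vs SO+3 for sphingolipids, sphinganine (SA) vs
SA+3 for dihydrosphingolipids. The package deliberately implements
descriptive flux quantities rather than a kinetic model — the readouts of
interest are levels and their relative changes, not rate constants:

* newly synthesized fraction $f = \mathrm{heavy}/(\mathrm{unlabeled} +
  \mathrm{heavy})$ per backbone, invariant to per-sample rescaling;
* percent change $100\,(v - r)/r$ of each channel versus a reference
  condition, computed on condition means (an option the data layout makes
  explicit: per-replicate changes can be recomputed from the returned
  table). Means-based ratios carry a small Jensen bias of order
  $\mathrm{CV}^2/n$ (≈ +3 percentage points on a 4-fold change at CV 15%,
  $n = 3$), which is below measurement noise at realistic settings but
  documented here because the suite's unbiasedness check must allow it;
* a classical one-way ANOVA per channel across conditions (delegated to
  `stats::oneway.test` with equal variances; the hand sum-of-squares
  decomposition is kept as a test oracle);
* optional seeded percentile bootstrap intervals (2,000 resamples by
  default) for the percent changes, since the source figures report none.

Amounts are assumed pre-normalized (per protein or per cell); species
tables are aggregated to class totals by summation over fatty-acyl chains,
with exact conservation checked and absent classes reported as zero rather
than missing.

## Oligomer stoichiometry from intact masses

Theoretical masses use the standard average residue-mass table plus one
water (18.0153 Da); average rather than monoisotopic masses match how
native MS and SEC-MALS report kDa-scale masses, and no post-translational
adjustments are applied. Stoichiometry of an observed mass $m$ against a
monomer $M$ is $k^\* = \arg\min_k |m - kM|/(kM)$ over $k \le k_{\max}$
(default 8), ties toward smaller $k$; the call is accepted within a 5%
relative-error tolerance — wide enough to accept a tetramer observed 3.4%
off its theoretical mass, tight enough to reject assignments that fit no
multiple. Cross-species identity uses a Needleman–Wunsch global alignment
(BLOSUM62, gap open 10 / extend 0.5) with identity counted over the full
alignment length.

The real reference sequences (human CERT isoform 1, NP_005704, and the
Drosophila orthologue) are **inputs, not package contents**: the package
ships only a clearly labelled synthetic 624-residue sequence
(`cert_synthetic.fasta`) for exercising the sequence code paths. Placing
the real FASTA files under `inst/extdata/reference/<accession>.fasta`
enables the sequence-dependent checks (the CCD 151–309 fragment mass, the
SEC-MALS dimer ratio, and the human–fly identity); without them those
checks fail with a clear message rather than silently passing on synthetic
data.

## What the generators emulate — and what they do not

Every generator is a pure function of its configuration including the
mandatory seed, and always returns its ground truth alongside the data.

* **Variant panels**: positions are a mixture of cluster draws (discretized
  Gaussian around a center, sd `sigma`, clamped to bounds) and uniform
  draws. Defaults mirror the cohort geometry: 17 variants on 624 residues,
  four centers, `sigma = 3` (the SRR hotspot spans about ten residues), and
  mixing 0.87 (the fraction of cohort variants falling in the inter-domain
  clusters). What is *not* emulated: mutational hotspots driven by CpG
  content, codon structure, or ascertainment bias in who gets sequenced —
  so a passing calibration says the test is fair against uniform placement,
  not that real gnomAD backgrounds are uniform.
* **Score tables**: background per-tool distributions are tool-shaped
  (truncated normal on the CADD PHRED scale, Beta for the [0,1] tools,
  normal for Eigen) and the pathogenic cohort is shifted by a configurable
  number of baseline SDs, then re-bounded. Inter-tool correlation, which is
  substantial in real predictors, is not modeled; rejection-rate summaries
  across tools are therefore slightly optimistic about joint behavior.
* **LCB datasets**: true backbone totals scale with a per-condition fold
  change, the heavy channel carries `label_fraction`, and measurements are
  multiplied by mean-one log-normal noise (CV 10% by default — typical for
  targeted lipidomics). Species tables are exact fixed-proportion splits of
  the emitted class totals, so aggregation is checkable to machine
  precision. Isotope-correction artifacts, partial isotopologues (M+1/M+2)
  and chain-length remodeling are out of scope: the tracer shifts the
  backbone by +3 or not at all.
* **Mass peaks**: exact multiples of the monomer with relative Gaussian
  noise; no charge-state or deconvolution artifacts.

## Degenerate inputs and edge behavior

Fewer than two usable positions, empty samples, all-missing score records,
zero backbone totals, zero-length peak lists and non-positive references
are all errors or flagged results with messages naming the offender —
never silent drops. `delta_g` with `"keep"` returns exactly 0 on
coincident positions; identical ANOVA groups return $F = 0,\ p = 1$;
`p_empirical` can never be 0 by construction.

## Known limitations

The clustering test is one-dimensional: it sees linear sequence distance,
not 3D proximity, so clusters that form only in the folded structure are
invisible to it. The exact composition of the original 17-position set and
whether the original null was sampled in nucleotide or protein space are
not recoverable from the source, so cohort-level p-values computed here
characterize the bundled panel, not the original computation. The flux
module quantifies descriptive changes, not synthesis rates. The
Mann–Whitney normal approximation should not be trusted on tiny tied
samples (use the exact path, which refuses ties, or aggregate). Stated
test problem sizes (1,000 calibration panels at $10^4$ permutations, 200
flux simulations, 100 oracle instances) are the package's chosen balance
of statistical resolution against a test suite that runs in a couple of
minutes.
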