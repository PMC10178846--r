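Package: certra
Title: Variant Clustering, Pathogenicity and Sphingolipid Flux Analyses for
    CerTra Syndrome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Reusable implementations of the computational analyses behind a
    study of the CerTra neurodevelopmental syndrome caused by dominant CERT1
    missense variants: linear spatial clustering of missense variants via a
    geometric-mean-distance permutation test with an exact enumeration
    oracle, in-silico pathogenicity classification (CADD, REVEL, M-CAP,
    Eigen) and cohort comparison with a from-scratch Mann-Whitney U test,
    stable-isotope long-chain-base sphingolipid flux quantification, protein
    oligomer stoichiometry inference from native-MS and SEC-MALS masses, and
    seeded synthetic-data generators so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
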