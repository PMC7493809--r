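Package: perturbtrack
Title: Analytic Detection of Mutationally Perturbed Functional Tracks in Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects genes whose somatic missense mutations are enriched in
    weighted functional sites (ligand-binding interfaces, domains, conserved
    positions) or across the whole gene. Per-position functionality is encoded
    as "tracks" with weights in [0,1]; mutational enrichment per track is
    scored analytically with closed-form means, variances and between-track
    covariances under a codon-aware background mutation model, replacing
    permutation tests. Correlated per-track Z scores are combined with a
    weighted Z-transform with correlation correction, calibrated per track by
    a minimum-mutation normality rule. Includes a synthetic-cohort generator,
    a permutation oracle for validating the closed forms, an expression-based
    mutation filter, and downstream analyses (interaction-site mutation
    entropy, gold-standard enrichment curves, Jaccard overlap, and per-gene
    mechanism reports).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
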