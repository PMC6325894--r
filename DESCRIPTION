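Package: phosevo
Title: Cross-Species Phosphosite Conservation, Propensity and Enrichment Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative phosphoproteomics toolkit for multi-species ortholog
    families. Integrates multi-source post-translational modification (PTM)
    site tables onto a non-redundant proteome, maps sites through ortholog
    multiple sequence alignments, scores cross-species conservation with
    11-residue window identity, predicts phosphorylation propensity from
    kinase-motif position-specific scoring matrix (PSSM) features with a
    deterministic maximum-margin classifier, estimates per-species false
    negative rates from perfectly conserved multiply-observed benchmark sites,
    and tests conservation and disease-variant proximity enrichment with an
    exact two-sided Fisher test. Ships a fully deterministic multi-species
    simulator with planted effects so every analysis stage has a recovery
    oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
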