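Package: progsig
Title: Marker-Based Stratification, Kaplan-Meier Cutoff Scans and
    Gene-Set Prognostic Signatures for Tumor Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives marker-gene-associated transcriptomic signatures and
    prognostic gene sets in tumor cohorts. Splits patients by the
    expression of a single marker gene (fixed percentile or an adaptive
    increment search), tests per-gene differential expression with
    Benjamini-Hochberg control, scans every expression cutoff of every
    gene for overall-survival separation by log-rank with Bonferroni
    correction, runs continuous-phenotype gene-set enrichment analysis
    with a Pearson ranking metric and phenotype permutations, maps
    enriched ontology terms into a 2D semantic landscape via Resnik
    information-content similarity and classical multidimensional
    scaling, and integrates the results into cross-cohort prognostic
    signatures. Ships a survival-aware synthetic cohort generator with
    planted differential-expression and prognostic structure for power
    and type-I studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    fgsea
Config/testthat/edition: 3
RoxygenNote: 7.3.3
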