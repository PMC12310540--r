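Package: pvhmr
Title: Molecular Prognostic Modelling of Polycythemia Vera
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the somatic mutation landscape of polycythemia
    vera (PV) cohorts and to model its prognostic consequences. Implements
    panel-variant retention rules and gene-by-patient mutation matrices,
    mutation co-occurrence analysis (pairwise association tests with
    Benjamini-Hochberg correction, BIC hill-climbing Bayesian network learning
    with bootstrap edge confidence, hierarchical clustering of genes), the
    PV-HMR three-tier genomic risk classification, an illness-death multistate
    survival model with transition-specific Cox regression and Aalen-Johansen
    state-occupation estimation, time-dependent prognostic performance metrics
    (Harrell's C, IPCW cumulative/dynamic AUC, IPCW Brier score), and a seeded
    synthetic clinical-genomic cohort generator for end-to-end testing and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
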