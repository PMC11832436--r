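Package: fgf21strat
Title: Stratified Comparative Transcriptomics for Index-Gene Expression Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies a patient transcriptome cohort by the expression status
    of an index gene (such as hepatic FGF21 in metabolic dysfunction-associated
    steatotic liver disease) relative to healthy controls, then runs the
    downstream comparative-genomics machinery: rank-sum differential expression
    with Benjamini-Hochberg FDR and fold-change filters, per-patient direction
    concordance, a patient-recurrence filter for candidate transcriptional
    regulators, weighted Kolmogorov-Smirnov gene-set and immune-marker
    enrichment with permutation-normalised enrichment scores, G-tests with
    Williams' correction, order-statistic confidence intervals for medians,
    Spearman correlation panels, and cross-species target-list validation.
    Includes a seeded synthetic-cohort generator with planted strata,
    expression programs and histology covariates for power, calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
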