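Package: tnbctype
Title: Molecular Subtyping of Triple-Negative Breast Cancer from Targeted Expression Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for calling the four triple-negative breast
    cancer molecular subtypes (BLIA, BLIS, LAR, MES) from targeted
    nCounter-style expression panels. Provides housekeeping-gene
    normalization with control-probe quality checks, nearest-shrunken-centroid
    (PAM) gene selection with quantile-centroid signature construction,
    frozen "addon" empirical-Bayes batch adjustment onto a training
    reference, per-sample subtype assignment by Spearman correlation with
    explicit unclassified and mixed-call rules, exact contingency-table and
    deviation-coded logistic association statistics, and survival analysis
    (Kaplan-Meier, log-rank, Cox proportional hazards with Schoenfeld
    diagnostics). Includes a synthetic-cohort generator so the full pipeline
    can be exercised and validated without access to patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
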