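# tnbctype

Molecular subtyping of triple-negative breast cancer (TNBC) from targeted
expression panels, as a reusable, testable R pipeline.

TNBC — breast cancer lacking ER and PR expression and HER2 amplification —
is biologically heterogeneous. Four expression-based molecular subtypes are
widely used: basal-like immune-activated (**BLIA**), basal-like
immunosuppressed (**BLIS**), luminal androgen receptor (**LAR**) and
mesenchymal (**MES**). They differ in prognosis (BLIS tends to have the
worst survival, LAR the best) and their prevalence differs across
racial/ethnic groups, so calling them reliably in a new cohort — typically
measured on a small NanoString nCounter codeset rather than a full
microarray — is a practical problem for translational groups. This package
implements that workflow end to end, for statisticians and bioinformaticians
who need to train or apply a centroid subtype signature, transfer it across
batches/platforms, and run the standard downstream association and survival
analyses.

## What the pipeline does

1. **QC + normalization** (`qc_assess`, `normalize_housekeeping`).
   nCounter-style control checks (background = mean + 2 sd of negative
   probes; positive-control scale factors), then housekeeping normalization:
   with `s_j = geomean(HK counts in sample j)`, every count is scaled by
   `geomean_j(s_j)/s_j` and log2-transformed.

2. **Signature training** (`fit_nsc`, `quantile_centroids`). Nearest
   shrunken centroids (PAM): for gene *i* and class *k*,
   `d_ik = (x̄_ik − x̄_i) / (m_k (s_i + s0))`, `m_k = sqrt(1/n_k − 1/n)`,
   soft-thresholded `d'_ik = sign(d_ik) max(|d_ik| − Δ, 0)`; Δ chosen by
   stratified cross-validation (largest Δ at minimum CV error). The shipped
   signature is the subtype-wise **quantile centroid**: each training
   sample's expression is rank-transformed to `(rank − 0.5)/G` within
   sample, and the centroid is the per-gene median over the subtype's
   samples.

3. **Frozen addon batch adjustment** (`fit_reference`, `addon_adjust`).
   ComBat-style empirical Bayes where the training batch's per-gene mean and
   variance are frozen: new data are standardized as
   `Z = (X − α̂_g)/σ̂_g`, the new batch's location/scale `(γ_g, δ²_g)` are
   shrunk by a parametric EB prior, and
   `X* = σ̂_g (Z − γ*_g)/δ*_g + α̂_g`. Training data are never touched, so
   prediction rules transfer. `pca_check` quantifies batch separation in
   PC1–2 before/after.

4. **Subtype calling** (`classify_cohort`). Each sample is assigned the
   subtype with the strongest Spearman correlation to the centroids;
   samples with no correlation above 0.55 are `UNCLASSIFIED`; classified
   samples whose top-two correlations differ by less than 0.1 are flagged
   *mixed* (the assignment stays the argmax).

5. **Association and survival statistics** (`fisher_exact_rc`,
   `fit_group_enrichment`, `derive_endpoints`, `km_fit`, `logrank_test`,
   `cox_fit`, `schoenfeld_check`). Exact r×c contingency tests;
   deviation-coded (sum-to-zero) logistic regression where each group's
   coefficient is its log-odds deviation from the group-average log-odds;
   overall and recurrence-free survival endpoints with the standard
   censoring rules; Kaplan–Meier, log-rank, Cox proportional hazards (Efron
   ties) and Schoenfeld-residual proportionality checks.

A synthetic-cohort generator (`cohort_spec`, `simulate_cohort`) produces
two-batch cohorts with known subtypes, batch effects, clinical covariates
and survival, so every stage is testable without patient data.

## Worked example

```r
library(tnbctype)

paths <- make_demo("demo", seed = 42)   # 84 training + 115 test samples
res <- run_pipeline(counts = paths$test_counts, clinical = paths$clinical,
                    train_counts = paths$train_counts,
                    train_labels = paths$train_labels,
                    out_dir = "demo/results", seed = 42)
res$calls
#> cohort_calls: 115 samples — BLIA 39, BLIS 47, LAR 25, MES 4; 0 unclassified, 7 mixed
res$pca
#> pca_check: batch separation 2.508 (pre) -> 0.005 (post)
```

The call summary partitions the 115 test samples across the four subtypes
(7 samples carry the mixed flag: their top-two centroid correlations are
within 0.1). The PCA line shows the batch-separation statistic (distance
between batch centroids in PC1–2 over mean within-batch spread) collapsing
from 2.508 to 0.005 after the addon adjustment; since the demo cohort is
simulated, the calls can be compared with the generator's truth
(`demo/test_true_labels.csv`), here 115/115 correct.

The published-cohort statistics run directly from summary counts:

```r
ref <- reference_tables()
fisher_exact_rc(ref$by_subtype$grade)$p_value
#> [1] 0.00124929
enr <- ref$enrichment
fit_group_enrichment(setNames(enr$blis_yes, enr$group),
                     setNames(enr$blis_no, enr$group))
#>             group yes no  coefficient        se           z          p
#> 1           White  12 21 -0.005822379 0.3460226 -0.01682659 0.98657496
#> 2        Hispanic  25 22  0.681626781 0.3114205  2.18876657 0.02861381
#> 3 AfricanAmerican   5  7  0.217321172 0.4750621  0.45745842 0.64734158
#> 4           Asian   4 17 -0.893125574 0.4568009 -1.95517474 0.05056245
```

The grade-by-subtype association is strong (p ≈ 0.0012, driven by the
excess of grade-2 tumors in LAR), and the enrichment fit shows Hispanic
patients over-represented in BLIS (coefficient 0.68, p ≈ 0.03) and Asian
patients under-represented (−0.89, p ≈ 0.05), each relative to the average
log-odds across the four groups.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/tnbc.R simulate --out demo --seed 42
Rscript inst/scripts/tnbc.R run --counts demo/test_counts.tsv \
    --train-counts demo/train_counts.tsv --train-labels demo/train_labels.csv \
    --clinical demo/clinical.csv --out demo/results --seed 42
```

## Vignette

`vignettes/tnbc-subtyping.Rmd` documents the model and its assumptions,
every tunable parameter, what the synthetic generator does and does not
emulate, and the package's design decisions.
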