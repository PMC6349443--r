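#' Control-probe quality assessment
#'
#' nCounter-style QC from internal control probes. Per sample: the
#' background estimate is `mean(negatives) + 2 * sd(negatives)`; the
#' positive-control scale factor is
#' `geomean(all positive counts) / geomean(sample's positive counts)`.
#' A sample is flagged `low_signal` when its factor falls outside
#' `[1/3, 3]`, `high_background` when more than half of its endogenous
#' probes fall below its background estimate, and `hk_failure` when any
#' housekeeping count is zero.
#'
#' @param raw a `raw_counts` object with at least one positive and one
#'   negative control probe.
#' @return A data frame of class `qc_report`: one row per sample with
#'   `pos_factor`, `background` and the three logical flags.
#' @export
qc_assess <- function(raw) {
  stopifnot(inherits(raw, "raw_counts"))
  pos <- raw$counts[raw$probe_class == "positive", , drop = FALSE]
  neg <- raw$counts[raw$probe_class == "negative", , drop = FALSE]
  if (nrow(pos) == 0 || nrow(neg) == 0)
    stopf("qc_assess needs positive and negative control probes")
  endo <- raw$counts[raw$probe_class == "endogenous", , drop = FALSE]
  hk <- raw$counts[raw$probe_class == "housekeeping", , drop = FALSE]
  grand <- geomean(pmax(pos, 0.5))
  factor_j <- apply(pos, 2, function(p) grand / geomean(pmax(p, 0.5)))
  background <- apply(neg, 2, function(x) mean(x) + 2 * stats::sd(x))
  below <- colMeans(sweep(endo, 2, background, `<`))
  rep <- data.frame(
    sample_id = colnames(raw$counts),
    pos_factor = unname(factor_j), background = unname(background),
    low_signal = unname(factor_j < 1 / 3 | factor_j > 3),
    high_background = unname(below > 0.5),
    hk_failure = unname(apply(hk, 2, function(x) any(x == 0))),
    stringsAsFactors = FALSE)
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Housekeeping-gene normalization with log2 transform
#'
#' Normalizes raw counts to absolute transcript abundance by the
#' housekeeping geometric mean, then log2-transforms. Per sample j the
#' scale is `s_j = geomean(housekeeping counts)`; every count is multiplied
#' by `geomean_j(s_j) / s_j`, which equalizes the housekeeping geometric
#' mean across samples, and the result is mapped through
#' `log2(x + offset)`. Control and housekeeping probes are dropped from the
#' output. Optionally the positive-control factors from [qc_assess()] are
#' applied first (`pos_norm = TRUE`, the nSolver order); default off, so
#' housekeeping normalization alone defines the output. Because the
#' per-sample scaling is a positive constant, within-sample ranks of
#' endogenous genes are preserved, so downstream Spearman classification is
#' invariant to both `pos_norm` and `offset`.
#'
#' @param raw a `raw_counts` object.
#' @param hk_genes housekeeping gene ids (default [default_housekeeping()]
#'   intersected with the annotated housekeeping probes).
#' @param offset pseudo-count added before log2 (default 1).
#' @param pos_norm apply positive-control factors before housekeeping
#'   normalization.
#' @return Numeric matrix (endogenous genes x samples) of log2 normalized
#'   expression, with attribute `"hk_scale"` holding the per-sample scale.
#' @export
normalize_housekeeping <- function(raw, hk_genes = NULL, offset = 1,
                                   pos_norm = FALSE) {
  stopifnot(inherits(raw, "raw_counts"))
  if (is.null(hk_genes)) {
    hk_genes <- names(raw$probe_class)[raw$probe_class == "housekeeping"]
    if (length(hk_genes) == 0) hk_genes <- intersect(default_housekeeping(),
                                                     rownames(raw$counts))
  }
  absent <- setdiff(hk_genes, rownames(raw$counts))
  if (length(absent))
    stopf("housekeeping gene(s) absent from counts: %s", paste(absent, collapse = ", "))
  counts <- raw$counts
  if (pos_norm) {
    qc <- qc_assess(raw)
    counts <- sweep(counts, 2, qc$pos_factor, `*`)
  }
  hk <- counts[hk_genes, , drop = FALSE]
  zero <- colnames(hk)[apply(hk, 2, function(x) any(x == 0))]
  if (length(zero))
    stopf("zero housekeeping count in sample(s) %s; run qc_assess",
          paste(zero, collapse = ", "))
  scale_j <- apply(hk, 2, geomean)
  factor_j <- geomean(scale_j) / scale_j
  endo <- counts[raw$probe_class == "endogenous", , drop = FALSE]
  out <- log2(sweep(endo, 2, factor_j, `*`) + offset)
  attr(out, "hk_scale") <- scale_j
  out
}
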