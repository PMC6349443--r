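#' Spearman rank correlation
#'
#' Pearson correlation of average ranks; ties receive average ranks.
#' Errors on constant input, where the correlation is undefined.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return The Spearman correlation coefficient.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 3) stopf("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("Spearman correlation undefined for a constant vector")
  stats::cor(x, y, method = "spearman")
}

#' Call the subtype of a single sample
#'
#' Computes the sample's Spearman correlation with each subtype centroid
#' over the shared signature genes and applies the decision rules:
#' the assigned subtype is the one with the strongest correlation;
#' a sample with no correlation above `tau_unclassified` (default 0.55,
#' boundary exclusive: exactly 0.55 is unclassified) is `UNCLASSIFIED`;
#' a classified sample whose top-two correlations differ by less than
#' `tau_mixed` (default 0.1) is flagged mixed with its top-two pair
#' recorded — the mixed flag does not change the assignment. Exact
#' correlation ties are broken by canonical subtype order and recorded.
#'
#' @param expr named numeric vector of per-gene expression.
#' @param centroids a [signature_centroids()] object; at least 90% of its
#'   genes should be present in `expr` (missing genes are dropped with a
#'   warning; < 3 shared genes is an error).
#' @param tau_unclassified correlation threshold for classification.
#' @param tau_mixed top-two gap threshold for the mixed flag.
#' @return A list of class `subtype_call`: `rho` (4 correlations),
#'   `assigned`, `unclassified`, `mixed`, `mixed_pair`, `gap`, `tied`.
#' @export
classify_sample <- function(expr, centroids, tau_unclassified = 0.55,
                            tau_mixed = 0.1) {
  stopifnot(inherits(centroids, "signature_centroids"))
  shared <- intersect(centroids$genes, names(expr))
  if (length(shared) < 3) stopf("fewer than 3 signature genes shared with sample")
  if (length(shared) < 0.9 * length(centroids$genes))
    warnf("only %d/%d signature genes present in sample", length(shared),
          length(centroids$genes))
  rho <- vapply(centroids$subtypes, function(k)
    spearman(expr[shared], centroids$centroids[k, shared]), 0)
  apply_call_rules(rho, tau_unclassified, tau_mixed)
}

# decision rules on a named correlation vector; exact ties broken by
# canonical subtype order; max(rho) exactly at the threshold -> UNCLASSIFIED
apply_call_rules <- function(rho, tau_unclassified = 0.55, tau_mixed = 0.1) {
  subtypes <- names(rho)
  ord <- order(-rho, match(subtypes, tnbc_subtypes()))
  top <- subtypes[ord[1]]
  gap <- rho[ord[1]] - rho[ord[2]]
  unclassified <- rho[ord[1]] <= tau_unclassified
  mixed <- !unclassified && gap < tau_mixed
  structure(list(
    rho = rho,
    assigned = if (unclassified) "UNCLASSIFIED" else top,
    unclassified = unclassified, mixed = mixed,
    mixed_pair = if (mixed) subtypes[ord[1:2]] else character(0),
    gap = unname(gap), tied = rho[ord[1]] == rho[ord[2]]
  ), class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat(sprintf("subtype_call: %s (rho = %s; gap = %.3f%s%s)\n", x$assigned,
              paste(sprintf("%s %.2f", names(x$rho), x$rho), collapse = ", "),
              x$gap, if (x$mixed) sprintf("; mixed %s",
                                          paste(x$mixed_pair, collapse = "-")) else "",
              if (x$tied) "; tied" else ""))
  invisible(x)
}

#' Call subtypes for a whole cohort
#'
#' Applies [classify_sample()] to every column of an expression matrix and
#' summarizes the calls. Per-sample failures (e.g. too few shared genes)
#' are recorded as `FAILED` rather than aborting the cohort.
#'
#' @param x genes x samples matrix of (batch-adjusted) log2 expression.
#' @param centroids a [signature_centroids()] object.
#' @inheritParams classify_sample
#' @return List of class `cohort_calls` with `calls` (data frame: sample
#'   id, four correlations, assigned subtype, flags, gap, mixed pair) and
#'   `summary` (counts per subtype, unclassified, failed, mixed counts by
#'   pair); the summary partitions the samples exactly.
#' @export
classify_cohort <- function(x, centroids, tau_unclassified = 0.55,
                            tau_mixed = 0.1) {
  stopifnot(inherits(centroids, "signature_centroids"))
  ids <- colnames(x)
  rows <- lapply(ids, function(j) {
    call <- tryCatch(
      classify_sample(x[, j], centroids, tau_unclassified, tau_mixed),
      error = function(e) e)
    if (inherits(call, "error")) {
      data.frame(sample_id = j, rho_BLIA = NA_real_, rho_BLIS = NA_real_,
                 rho_LAR = NA_real_, rho_MES = NA_real_, assigned = "FAILED",
                 unclassified = NA, mixed = NA, mixed_pair = "",
                 gap = NA_real_, stringsAsFactors = FALSE)
    } else {
      rho <- call$rho[tnbc_subtypes()]
      data.frame(sample_id = j, rho_BLIA = rho[["BLIA"]],
                 rho_BLIS = rho[["BLIS"]], rho_LAR = rho[["LAR"]],
                 rho_MES = rho[["MES"]], assigned = call$assigned,
                 unclassified = call$unclassified, mixed = call$mixed,
                 mixed_pair = paste(call$mixed_pair, collapse = "-"),
                 gap = call$gap, stringsAsFactors = FALSE)
    }
  })
  calls <- do.call(rbind, rows)
  counts <- vapply(tnbc_subtypes(), function(k) sum(calls$assigned == k), 0L)
  mixed_tab <- table(calls$mixed_pair[!is.na(calls$mixed) & calls$mixed])
  structure(list(
    calls = calls,
    summary = list(
      n_samples = length(ids), counts = counts,
      n_unclassified = sum(calls$assigned == "UNCLASSIFIED"),
      n_failed = sum(calls$assigned == "FAILED"),
      n_mixed = sum(calls$mixed, na.rm = TRUE),
      mixed_by_pair = as.list(mixed_tab),
      tau_unclassified = tau_unclassified, tau_mixed = tau_mixed)
  ), class = "cohort_calls")
}

#' @export
print.cohort_calls <- function(x, ...) {
  s <- x$summary
  cat(sprintf("cohort_calls: %d samples — %s; %d unclassified, %d mixed\n",
              s$n_samples,
              paste(sprintf("%s %d", names(s$counts), s$counts), collapse = ", "),
              s$n_unclassified, s$n_mixed))
  invisible(x)
}

#' Concordance of calls with reference labels
#'
#' Counts inconsistencies between assigned subtypes and reference labels
#' among classified samples; unclassified/failed samples are reported
#' separately, never counted as inconsistent.
#'
#' @param calls a `cohort_calls` object or its `calls` data frame.
#' @param reference named character vector of reference labels (names =
#'   sample ids, covering all call ids).
#' @return List with `n_inconsistent`, `n_classified`, `n_unclassified`,
#'   `accuracy` (among classified) and `confusion` (reference x assigned).
#' @export
concordance <- function(calls, reference) {
  if (inherits(calls, "cohort_calls")) calls <- calls$calls
  if (is.null(names(reference))) stopf("reference labels must be named by sample id")
  missing <- setdiff(calls$sample_id, names(reference))
  if (length(missing))
    stopf("no reference label for sample(s): %s", paste(missing, collapse = ", "))
  ref <- reference[calls$sample_id]
  classified <- calls$assigned %in% tnbc_subtypes()
  n_inc <- sum(calls$assigned[classified] != ref[classified])
  conf <- table(reference = ref[classified],
                assigned = factor(calls$assigned[classified],
                                  levels = tnbc_subtypes()))
  list(n_inconsistent = n_inc, n_classified = sum(classified),
       n_unclassified = sum(!classified),
       accuracy = if (any(classified)) 1 - n_inc / sum(classified) else NA_real_,
       confusion = conf)
}
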