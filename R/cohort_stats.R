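#' Exact r x c contingency-table test
#'
#' Two-sided Fisher exact test for an r x c table of counts: the p-value is
#' the total conditional probability (multivariate hypergeometric given the
#' margins) of all tables at most as probable as the observed one. All-zero
#' rows and columns are dropped first; a table degenerate after dropping
#' (a single non-empty row or column) returns p = 1 with a warning. Exact
#' enumeration (the network algorithm) is used up to `max_n` total counts;
#' larger tables require `simulate = TRUE`, which estimates the p-value by
#' Monte-Carlo sampling of tables with the observed margins.
#'
#' @param tab matrix of non-negative integer counts (>= 2 x 2 after
#'   dropping empty rows/columns).
#' @param simulate use Monte-Carlo estimation instead of exact enumeration.
#' @param B number of Monte-Carlo draws.
#' @param seed seed for the Monte-Carlo mode.
#' @param max_n largest total count admitted to exact mode.
#' @return List with `p_value` and `method`.
#' @export
fisher_exact_rc <- function(tab, simulate = FALSE, B = 1e5, seed = 1L,
                            max_n = 10000) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("table must contain non-negative integer counts")
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    warnf("degenerate table (single non-empty row or column); p = 1")
    return(list(p_value = 1, method = "degenerate"))
  }
  if (!simulate && sum(tab) > max_n)
    stopf("N = %d exceeds exact-mode budget (%d); use simulate = TRUE",
          sum(tab), max_n)
  if (simulate) {
    res <- with_seed(seed,
      stats::fisher.test(tab, simulate.p.value = TRUE, B = B))
    list(p_value = res$p.value, method = sprintf("monte-carlo (B = %g)", B))
  } else {
    res <- stats::fisher.test(tab, workspace = 2e7)
    list(p_value = res$p.value, method = "exact")
  }
}

#' Deviation-coded logistic enrichment of a subtype across groups
#'
#' Fits a binomial logistic model of subtype membership (yes/no) on a
#' single K-level group factor with sum-to-zero (deviation) coding, so
#' each group's coefficient is its log-odds deviation from the unweighted
#' average of the group log-odds; coefficients over all K groups sum to
#' zero, and the K-th is recovered as minus the sum of the others, with
#' its standard error from the coded design's covariance. For this
#' saturated one-factor model the fitted coefficients equal the closed-form
#' log-odds deviations. A group with zero yes or zero no counts makes the
#' log-odds infinite and is an error unless `continuity = TRUE`, which adds
#' 0.5 to every cell (reported in the result).
#'
#' @param yes_counts,no_counts named integer vectors of per-group counts
#'   (same group order).
#' @return Data frame of class `enrichment_fit`: group, yes, no,
#'   coefficient, se, z, p (Wald).
#' @export
fit_group_enrichment <- function(yes_counts, no_counts, continuity = FALSE) {
  if (length(yes_counts) != length(no_counts))
    stopf("yes_counts and no_counts must have equal length")
  k <- length(yes_counts)
  if (k < 2) stopf("need at least 2 groups")
  groups <- names(yes_counts)
  if (is.null(groups)) groups <- paste0("group", seq_len(k))
  if (any(yes_counts + no_counts == 0)) stopf("group with no observations")
  sep <- yes_counts == 0 | no_counts == 0
  if (any(sep)) {
    if (!continuity)
      stopf("group(s) with zero yes or zero no counts (%s): log-odds infinite; set continuity = TRUE to add 0.5",
            paste(groups[sep], collapse = ", "))
    warnf("continuity correction of 0.5 applied to all cells")
    yes_counts <- yes_counts + 0.5
    no_counts <- no_counts + 0.5
  }
  g <- factor(groups, levels = groups)
  # the continuity-corrected counts are deliberately non-integer
  fit <- withCallingHandlers(
    stats::glm(cbind(yes_counts, no_counts) ~ C(g, stats::contr.sum),
               family = stats::binomial()),
    warning = function(w) {
      if (grepl("non-integer counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)[-1]                 # K-1 deviation coefficients
  V <- stats::vcov(fit)[-1, -1, drop = FALSE]
  coefs <- c(beta, -sum(beta))
  ses <- c(sqrt(diag(V)), sqrt(sum(V)))        # var(-sum) = 1' V 1
  z <- coefs / ses
  out <- data.frame(group = groups, yes = as.numeric(yes_counts),
                    no = as.numeric(no_counts),
                    coefficient = unname(coefs), se = unname(ses),
                    z = unname(z), p = unname(2 * stats::pnorm(-abs(z))),
                    stringsAsFactors = FALSE)
  attr(out, "continuity") <- any(sep)
  class(out) <- c("enrichment_fit", "data.frame")
  out
}

#' Build a contingency table from clinical data and subtype calls
#'
#' Tallies two categorical variables against each other. Variables are
#' clinical columns, or `"subtype"`, which takes the assigned subtype from
#' `calls` (unclassified/failed samples excluded). Missing values (empty
#' string or `NA`) are excluded row-wise under the default policy.
#'
#' @param clinical a `clinical_table`.
#' @param calls optional `cohort_calls` (required when a variable is
#'   `"subtype"`).
#' @param row_var,col_var variable names.
#' @param missing_policy `"exclude"` (drop samples missing either
#'   variable) or `"keep"` (keep a `"missing"` level).
#' @return Integer matrix of counts (rows = `row_var` levels).
#' @export
build_table <- function(clinical, calls = NULL, row_var, col_var,
                        missing_policy = c("exclude", "keep")) {
  missing_policy <- match.arg(missing_policy)
  if (nrow(clinical) == 0) stopf("empty cohort")
  get_var <- function(v) {
    if (v == "subtype") {
      if (is.null(calls)) stopf("calls required for the subtype variable")
      df <- if (inherits(calls, "cohort_calls")) calls$calls else calls
      x <- df$assigned[match(clinical$sample_id, df$sample_id)]
      x[!x %in% tnbc_subtypes()] <- NA
      factor(x, levels = tnbc_subtypes())
    } else {
      if (!v %in% names(clinical)) stopf("unknown variable: %s", v)
      x <- as.character(clinical[[v]])
      x[x == ""] <- NA
      x
    }
  }
  r <- get_var(row_var); c_ <- get_var(col_var)
  if (missing_policy == "exclude") {
    keep <- !is.na(r) & !is.na(c_)
    r <- r[keep]; c_ <- c_[keep]
  } else {
    r <- ifelse(is.na(as.character(r)), "missing", as.character(r))
    c_ <- ifelse(is.na(as.character(c_)), "missing", as.character(c_))
  }
  tb <- table(r, c_)
  m <- matrix(as.integer(tb), nrow(tb),
              dimnames = stats::setNames(dimnames(tb), c(row_var, col_var)))
  m
}
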