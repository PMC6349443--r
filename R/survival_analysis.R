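#' Derive overall and recurrence-free survival endpoints
#'
#' Computes per-sample endpoint time/event pairs from the clinical dates,
#' in months (days / 30.4375). Overall survival runs from surgery to death
#' from any cause, censored at last contact. Recurrence-free survival runs
#' from surgery to breast-cancer recurrence; without a recurrence it is
#' censored at death when the cause of death was not breast cancer,
#' otherwise at last contact. A death from breast cancer with no recorded
#' recurrence is censored at death and flagged in `rfs_flag` (the records
#' are surfaced rather than silently treated as events).
#'
#' @param clinical a `clinical_table`.
#' @return Data frame of class `survival_outcome`: `sample_id`, `os_time`,
#'   `os_event`, `rfs_time`, `rfs_event`, `rfs_flag`.
#' @export
derive_endpoints <- function(clinical) {
  stopifnot(inherits(clinical, "clinical_table"))
  as_d <- function(x) as.Date(ifelse(is.na(x) | x == "", NA, x))
  surg <- as_d(clinical$surgery_date)
  rec <- as_d(clinical$recurrence_date)
  dth <- as_d(clinical$death_date)
  lc <- as_d(clinical$last_contact_date)
  if (anyNA(surg)) stopf("surgery_date missing for sample(s): %s",
    paste(clinical$sample_id[is.na(surg)], collapse = ", "))
  if (any(is.na(rec) & is.na(dth) & is.na(lc)))
    stopf("no follow-up date for sample(s): %s",
          paste(clinical$sample_id[is.na(rec) & is.na(dth) & is.na(lc)],
                collapse = ", "))
  died <- !is.na(dth)
  bc_death <- died & clinical$death_from_bc == "yes"
  os_end <- as.Date(ifelse(died, dth, lc), origin = "1970-01-01")
  os_time <- months_between(surg, os_end)

  recurred <- !is.na(rec)
  rfs_end <- as.Date(ifelse(recurred, rec, ifelse(died, dth, lc)),
                     origin = "1970-01-01")
  rfs_time <- months_between(surg, rfs_end)
  rfs_flag <- !recurred & bc_death
  out <- data.frame(sample_id = clinical$sample_id,
                    os_time = os_time, os_event = as.integer(died),
                    rfs_time = rfs_time, rfs_event = as.integer(recurred),
                    rfs_flag = rfs_flag, stringsAsFactors = FALSE)
  class(out) <- c("survival_outcome", "data.frame")
  out
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate `S(t) = prod_{t_i <= t} (1 - d_i / n_i)`, with
#' the at-risk and cumulative-event counts used in at-risk tables.
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators.
#' @return Data frame: `time`, `n_risk`, `n_event`, `n_censor`, `surv`
#'   (right-continuous, `S(0) = 1`), `cum_events`.
#' @export
km_fit <- function(times, events) {
  if (length(times) < 1) stopf("need at least one observation")
  if (any(times < 0)) stopf("negative times")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, surv = fit$surv,
             cum_events = cumsum(fit$n.event))
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected log-rank chi-square over the pooled
#' event times, with `#groups - 1` degrees of freedom.
#'
#' @param times,events as in [km_fit()].
#' @param group group label per subject (>= 2 non-empty groups).
#' @return List: `chisq`, `df`, `p_value`, `obs`, `exp` per group.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stopf("need at least 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1
  list(chisq = sd$chisq, df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       obs = sd$obs, exp = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Fits a Cox model of the given endpoint on a covariate data frame
#' (factors one-hot coded against configurable reference levels), Efron
#' tie handling by default, and returns hazard ratios with Wald 95%
#' confidence intervals. The fitted `survival::coxph` object is kept for
#' diagnostics.
#'
#' @param times,events endpoint per subject.
#' @param covariates data frame of covariates (factors or numerics).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param ref_levels named list: reference level per factor covariate
#'   (e.g. `list(subtype = "BLIA")`).
#' @return Object of class `cox_fit`: `table` (coef, HR, CI, p per term),
#'   `loglik`, `converged`, and the underlying `fit`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow"),
                    ref_levels = NULL) {
  ties <- match.arg(ties)
  if (any(times < 0)) stopf("negative times")
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  for (v in names(df)) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (is.factor(df[[v]]) && !is.null(ref_levels[[v]]))
      df[[v]] <- stats::relevel(df[[v]], ref = ref_levels[[v]])
  }
  df$.time <- times; df$.event <- events
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(setdiff(names(df), c(".time", ".event")),
                                       collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = ties)
  if (anyNA(stats::coef(fit)))
    stopf("Cox model not full rank; drop or merge covariate levels")
  s <- summary(fit)
  tab <- data.frame(term = rownames(s$coefficients),
                    coef = s$coefficients[, "coef"],
                    hr = s$coefficients[, "exp(coef)"],
                    se = s$coefficients[, "se(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2],
                 converged = fit$info["convergence"] %||% TRUE, fit = fit),
            class = "cox_fit")
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' @export
print.cox_fit <- function(x, ...) {
  cat("cox_fit:\n")
  print(transform(x$table, hr = signif(hr, 4), p = signif(p, 3))[
    , c("term", "hr", "ci_lower", "ci_upper", "p")])
  invisible(x)
}

#' Schoenfeld-residual proportionality check
#'
#' Score test for a zero slope of the scaled Schoenfeld residuals against
#' Kaplan-Meier-transformed time, per covariate and globally (the
#' `cox.zph` diagnostic); a small p-value indicates a time-varying effect,
#' i.e. non-proportional hazards.
#'
#' @param fit a `cox_fit`.
#' @return Data frame: term, chisq, df, p; plus attribute `"zph"` with the
#'   full `survival::cox.zph` object (for residual-trend plots).
#' @export
schoenfeld_check <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  nev <- sum(fit$fit$y[, ncol(fit$fit$y)])
  if (nev < 3) stopf("need at least 3 events")
  z <- survival::cox.zph(fit$fit, transform = "km")
  out <- data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
                    df = z$table[, "df"], p = z$table[, "p"],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "zph") <- z
  out
}
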