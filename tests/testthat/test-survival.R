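mk_clin <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  defaults <- data.frame(age_dx = 55, group = "White", family_history = "no",
                         detection = "lump", grade = 3L, stage = 2L,
                         tumor_size = "T2", node_positive = "no")
  clinical_table(cbind(df["sample_id"], defaults,
                       df[setdiff(names(df), "sample_id")]))
}

test_that("endpoints follow the censoring rules", {
  d0 <- "2005-01-01"
  clin <- mk_clin(
    # alive, no recurrence: both endpoints censored at last contact
    list(sample_id = "alive", surgery_date = d0, recurrence_date = "",
         death_date = "", death_from_bc = "", last_contact_date = "2007-01-01"),
    # death from other cause at ~30 months, no recurrence
    list(sample_id = "other_death", surgery_date = d0, recurrence_date = "",
         death_date = "2007-07-04", death_from_bc = "no",
         last_contact_date = "2007-07-04"),
    # recurrence at ~12 then breast-cancer death at ~20 months
    list(sample_id = "rec_then_death", surgery_date = d0,
         recurrence_date = "2006-01-01", death_date = "2006-09-01",
         death_from_bc = "yes", last_contact_date = "2006-09-01"),
    # breast-cancer death with no recorded recurrence: censored + flagged
    list(sample_id = "bc_death_norec", surgery_date = d0, recurrence_date = "",
         death_date = "2006-01-01", death_from_bc = "yes",
         last_contact_date = "2006-01-01"))
  eps <- derive_endpoints(clin)
  rownames(eps) <- eps$sample_id
  expect_equal(eps["alive", "os_event"], 0L)
  expect_equal(eps["alive", "rfs_event"], 0L)
  expect_equal(eps["alive", "os_time"], eps["alive", "rfs_time"])
  expect_equal(eps["alive", "os_time"], 730 / 30.4375)

  expect_equal(eps["other_death", "os_event"], 1L)
  expect_equal(eps["other_death", "rfs_event"], 0L)    # censored at death
  expect_equal(eps["other_death", "os_time"], eps["other_death", "rfs_time"])

  expect_equal(eps["rec_then_death", "rfs_event"], 1L)
  expect_lt(eps["rec_then_death", "rfs_time"], eps["rec_then_death", "os_time"])
  expect_equal(eps["rec_then_death", "os_event"], 1L)

  expect_equal(eps["bc_death_norec", "rfs_event"], 0L)
  expect_true(eps["bc_death_norec", "rfs_flag"])
})

test_that("KM estimate matches the hand computation", {
  # times (2, 4+, 5): S = 2/3 on [2,5), then 0 at 5
  km <- km_fit(c(2, 4, 5), c(1, 0, 1))
  expect_equal(km$surv[km$time == 2], 2 / 3)
  expect_equal(km$surv[km$time == 5], 0)
  expect_equal(km$n_risk, c(3, 2, 1))
  expect_equal(km$cum_events, c(1, 1, 2))
  # no censoring: KM equals the empirical survival function
  t2 <- c(1, 3, 7, 9)
  km2 <- km_fit(t2, rep(1, 4))
  expect_equal(km2$surv, 1 - seq_along(t2) / 4)
  # all censored: S stays at 1
  expect_true(all(km_fit(t2, rep(0, 4))$surv == 1))
  expect_error(km_fit(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM on merged identical groups equals KM on either group", {
  set.seed(4)
  t1 <- rexp(30, 0.1); e1 <- rbinom(30, 1, 0.7)
  km_one <- km_fit(t1, e1)
  km_merged <- km_fit(c(t1, t1), c(e1, e1))
  expect_equal(km_merged$surv, km_one$surv)
  expect_equal(km_merged$time, km_one$time)
})

test_that("log-rank matches a hand-computed O-E statistic", {
  # independent textbook computation over pooled event times
  times <- c(1, 2, 3, 4, 5, 6); events <- c(1, 1, 0, 1, 0, 0)
  group <- c("a", "b", "a", "b", "a", "b")
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == "a")
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & group == "a")
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  oracle <- o_minus_e^2 / v
  res <- logrank_test(times, events, group)
  expect_equal(res$chisq, oracle, tolerance = 1e-10)
  expect_equal(res$df, 1)
})

test_that("identical groups give a zero log-rank statistic", {
  set.seed(5)
  t1 <- rexp(20, 0.1); e1 <- rbinom(20, 1, 0.8)
  res <- logrank_test(c(t1, t1), c(e1, e1), rep(c("x", "y"), each = 20))
  expect_equal(res$chisq, 0, tolerance = 1e-10)
  expect_equal(res$p_value, 1)
  expect_error(logrank_test(t1, e1, rep("x", 20)), "2 groups")
})

test_that("two-group log-rank equals the Cox score test with Breslow ties", {
  set.seed(6)
  n <- 40
  times <- round(rexp(n, 0.05), 6)           # continuous, tie-free
  events <- rbinom(n, 1, 0.8)
  group <- rep(c("a", "b"), each = n / 2)
  lr <- logrank_test(times, events, group)
  cf <- cox_fit(times, events, data.frame(g = group), ties = "breslow")
  score <- summary(cf$fit)$sctest[["test"]]
  expect_equal(lr$chisq, score, tolerance = 1e-8)
})

test_that("Cox coefficient matches brute-force partial-likelihood maximization", {
  times <- c(2, 5, 6, 9, 12); events <- c(1, 1, 0, 1, 1)
  z <- c(0, 1, 1, 0, 1)
  # written-out partial likelihood (no ties), maximized by golden section
  negpl <- function(b) {
    ll <- 0
    for (i in which(events == 1)) {
      risk <- times >= times[i]
      ll <- ll + b * z[i] - log(sum(exp(b * z[risk])))
    }
    -ll
  }
  oracle <- optimize(negpl, c(-10, 10), tol = 1e-10)$minimum
  cf <- cox_fit(times, events, data.frame(z = z))
  expect_equal(cf$table$coef, oracle, tolerance = 1e-6)
  expect_true(cf$table$ci_lower < cf$table$hr & cf$table$hr < cf$table$ci_upper)
})

test_that("partial likelihood is invariant to covariate location shifts", {
  set.seed(8)
  n <- 60
  z <- rnorm(n)
  times <- rexp(n, 0.05 * exp(0.5 * z)); events <- rbinom(n, 1, 0.85)
  f1 <- cox_fit(times, events, data.frame(z = z))
  f2 <- cox_fit(times, events, data.frame(z = z + 100))
  expect_equal(f1$table$coef, f2$table$coef, tolerance = 1e-8)
})

test_that("null covariates give hazard ratios near 1", {
  set.seed(9)
  cover <- vapply(1:100, function(r) {
    n <- 50
    z <- rbinom(n, 1, 0.5)
    times <- rexp(n, 0.05); events <- rbinom(n, 1, 0.8)
    cf <- cox_fit(times, events, data.frame(z = z))
    abs(cf$table$coef) < 3 * cf$table$se
  }, NA)
  expect_gte(mean(cover), 0.95)
})

test_that("non-full-rank covariates are rejected", {
  set.seed(10)
  z <- rbinom(20, 1, 0.5)
  expect_error(cox_fit(rexp(20, 0.1), rbinom(20, 1, 0.8),
                       data.frame(a = z, b = 2 * z)), "full rank")
})

test_that("Schoenfeld check keeps size under proportional hazards", {
  set.seed(11)
  rej <- vapply(1:100, function(r) {
    n <- 80
    z <- rnorm(n)
    times <- rexp(n, 0.05 * exp(0.4 * z))
    events <- rbinom(n, 1, 0.9)
    cf <- cox_fit(times, events, data.frame(z = z))
    schoenfeld_check(cf)$p[1] < 0.05
  }, NA)
  expect_lt(mean(rej), 0.12)
})

test_that("Schoenfeld check detects a crossing time-varying effect", {
  set.seed(12)
  rej <- vapply(1:20, function(r) {
    n <- 300
    z <- rbinom(n, 1, 0.5)
    # effect reverses sign at t = 10: early hazard up, late hazard down
    early <- rexp(n, 0.08 * exp(1.2 * z))
    late <- 10 + rexp(n, 0.08 * exp(-1.2 * z))
    times <- ifelse(early < 10, early, late)
    events <- rep(1, n)
    cf <- cox_fit(times, events, data.frame(z = z))
    schoenfeld_check(cf)$p[1] < 0.05
  }, NA)
  expect_gt(mean(rej), 0.8)
})

test_that("scaled Schoenfeld residuals center on zero", {
  set.seed(13)
  n <- 60
  z <- rnorm(n)
  times <- rexp(n, 0.05 * exp(0.5 * z)); events <- rbinom(n, 1, 0.9)
  cf <- cox_fit(times, events, data.frame(z = z))
  res <- residuals(cf$fit, type = "schoenfeld")
  expect_lt(abs(sum(res)), 1e-8)    # score identity at the MLE
  expect_error(suppressWarnings(schoenfeld_check(
    cox_fit(c(1, 2, 3), c(1, 0, 0), data.frame(z = c(0, 1, 0))))), "3 events")
})
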