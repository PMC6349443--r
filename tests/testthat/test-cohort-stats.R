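# exhaustive enumeration of r x c tables with fixed margins (oracle)
enumerate_tables <- function(row_sums, col_sums) {
  r <- length(row_sums)
  out <- list()
  fill <- function(tab, i) {
    if (i == r) {
      last <- col_sums - colSums(tab)
      if (all(last >= 0)) out[[length(out) + 1L]] <<- rbind(tab, last)
      return(invisible())
    }
    cells <- expand_rows(row_sums[i], pmin(col_sums - colSums(tab), row_sums[i]))
    for (j in seq_len(nrow(cells))) fill(rbind(tab, cells[j, ]), i + 1L)
  }
  expand_rows <- function(total, caps) {
    if (length(caps) == 1) {
      if (total <= caps) return(matrix(total, 1, 1)) else return(matrix(0, 0, 1))
    }
    do.call(rbind, lapply(0:min(total, caps[1]), function(v) {
      rest <- expand_rows(total - v, caps[-1])
      if (nrow(rest) == 0) return(matrix(0, 0, length(caps)))
      cbind(v, rest)
    }))
  }
  fill(matrix(0, 0, length(col_sums)), 1L)
  out
}

table_log_prob <- function(tab) {
  sum(lfactorial(rowSums(tab))) + sum(lfactorial(colSums(tab))) -
    lfactorial(sum(tab)) - sum(lfactorial(tab))
}

test_that("2x2 exact p matches the closed-form hypergeometric computation", {
  tab <- matrix(c(2, 36, 5, 41), 2, 2)   # [[2,5],[36,41]]
  # enumerate the 2x2 conditional distribution directly via dhyper
  k <- sum(tab[1, ]); m <- sum(tab[, 1]); n <- sum(tab[, 2])
  probs <- dhyper(0:min(k, m), m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  oracle <- sum(probs[probs <= obs * (1 + 1e-7)])
  expect_equal(fisher_exact_rc(tab)$p_value, oracle, tolerance = 1e-9)
})

test_that("r x c exact p matches exhaustive enumeration on small tables", {
  tab <- matrix(c(3, 1, 2, 2, 4, 1, 1, 2, 3), 3, 3)
  tabs <- enumerate_tables(rowSums(tab), colSums(tab))
  lp <- vapply(tabs, table_log_prob, 0)
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-10)   # conditional law sums to 1
  obs <- table_log_prob(tab)
  oracle <- sum(exp(lp[lp <= obs + 1e-7]))
  expect_equal(fisher_exact_rc(tab)$p_value, oracle, tolerance = 1e-7)
})

test_that("empty rows and columns do not affect the test", {
  tab <- matrix(c(10, 5, 10, 1, 26, 41, 14, 3), 2, 4, byrow = TRUE)
  padded <- rbind(cbind(tab, 0), 0)
  expect_equal(fisher_exact_rc(padded)$p_value, fisher_exact_rc(tab)$p_value)
})

test_that("the p-value is invariant to permutation and transposition", {
  tab <- matrix(c(2, 5, 10, 0, 36, 41, 13, 4), 2, 4, byrow = TRUE)
  p <- fisher_exact_rc(tab)$p_value
  expect_equal(fisher_exact_rc(tab[, c(3, 1, 4, 2)])$p_value, p)
  expect_equal(fisher_exact_rc(tab[2:1, ])$p_value, p)
  expect_equal(fisher_exact_rc(t(tab))$p_value, p)
})

test_that("degenerate and oversized tables are handled explicitly", {
  expect_warning(res <- fisher_exact_rc(matrix(c(3, 4, 0, 0), 2, 2)),
                 "degenerate")
  expect_equal(res$p_value, 1)
  big <- matrix(c(6000, 5000, 5000, 6000), 2, 2)
  expect_error(fisher_exact_rc(big), "simulate")
  expect_error(fisher_exact_rc(matrix(c(1.5, 2, 3, 4), 2, 2)), "integer")
})

test_that("Monte-Carlo mode converges to the exact p on small tables", {
  tab <- matrix(c(2, 5, 10, 0, 36, 41, 13, 4), 2, 4, byrow = TRUE)
  exact <- fisher_exact_rc(tab)$p_value
  mc <- fisher_exact_rc(tab, simulate = TRUE, B = 2e5, seed = 7)$p_value
  se <- sqrt(exact * (1 - exact) / 2e5)
  expect_lt(abs(mc - exact), 3 * se + 1e-5)
})

test_that("deviation-coded coefficients equal the closed-form log-odds deviations", {
  yes <- c(W = 12, H = 25, A = 5, As = 4)
  no <- c(W = 21, H = 22, A = 7, As = 17)
  fit <- fit_group_enrichment(yes, no)
  lo <- log(yes / no)
  expect_equal(fit$coefficient, unname(lo - mean(lo)), tolerance = 1e-8)
  expect_lt(abs(sum(fit$coefficient)), 1e-8)
})

test_that("relabeling groups permutes coefficients identically", {
  yes <- c(a = 9, b = 6, c = 2, d = 8); no <- c(a = 24, b = 41, c = 10, d = 13)
  f1 <- fit_group_enrichment(yes, no)
  perm <- c(3, 1, 4, 2)
  f2 <- fit_group_enrichment(yes[perm], no[perm])
  expect_equal(f2$coefficient, f1$coefficient[perm], tolerance = 1e-10)
  expect_equal(f2$p, f1$p[perm], tolerance = 1e-8)
})

test_that("equal group proportions give zero coefficients", {
  fit <- fit_group_enrichment(c(5, 10, 20), c(10, 20, 40))
  expect_equal(fit$coefficient, rep(0, 3), tolerance = 1e-10)
})

test_that("separated groups error unless the continuity option is set", {
  expect_error(fit_group_enrichment(c(a = 0, b = 5), c(a = 10, b = 5)),
               "continuity")
  expect_warning(fit <- fit_group_enrichment(c(a = 0, b = 5), c(a = 10, b = 5),
                                             continuity = TRUE), "0.5")
  expect_true(all(is.finite(fit$coefficient)))
})

test_that("contingency tables are built with the documented missing policy", {
  spec <- cohort_spec(n_samples = 60, n_test = 30, seed = 19,
                      subtype_props = rep(0.25, 4))
  res <- run_synthetic_pipeline(spec)
  clin <- clinical_table(res$cohort$clinical[
    res$cohort$clinical$sample_id %in% res$calls$calls$sample_id, ])
  tab <- build_table(clin, res$calls, "grade", "subtype")
  # tally oracle: direct group-by count
  df <- merge(as.data.frame(clin), res$calls$calls, by = "sample_id")
  df <- df[df$assigned %in% tnbc_subtypes(), ]
  expect_equal(sum(tab), nrow(df))
  for (g in rownames(tab)) for (k in colnames(tab))
    expect_equal(tab[g, k], sum(df$grade == g & df$assigned == k))
  # missing values excluded from margins
  clin2 <- clin; clin2$grade[1:5] <- NA
  tab2 <- build_table(clinical_table(clin2), res$calls, "grade", "subtype")
  expect_equal(sum(tab2),
               sum(!is.na(clin2$grade) &
                     res$calls$calls$assigned[match(clin2$sample_id,
                                                    res$calls$calls$sample_id)] %in%
                     tnbc_subtypes()))
  expect_error(build_table(clin, res$calls, "nonexistent", "subtype"), "unknown")
  expect_error(build_table(clin[0, ], res$calls, "grade", "subtype"), "empty")
})
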