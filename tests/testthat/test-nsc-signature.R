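# independent transcription of the shrunken-centroid formulas, vectorized
# differently from the implementation (per-gene loops, no sweeps)
nsc_oracle <- function(x, labels, delta) {
  classes <- sort(unique(labels))
  n <- ncol(x); K <- length(classes)
  out_d <- matrix(0, nrow(x), K, dimnames = list(rownames(x), classes))
  out_c <- out_d
  s <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    ss <- 0
    for (k in classes) {
      xi <- x[i, labels == k]
      ss <- ss + sum((xi - mean(xi))^2)
    }
    s[i] <- sqrt(ss / (n - K))
  }
  s0 <- median(s)
  for (i in seq_len(nrow(x))) {
    for (k in classes) {
      nk <- sum(labels == k)
      mk <- sqrt(1 / nk - 1 / n)
      d <- (mean(x[i, labels == k]) - mean(x[i, ])) / (mk * (s[i] + s0))
      dp <- sign(d) * max(abs(d) - delta, 0)
      out_d[i, k] <- dp
      out_c[i, k] <- mean(x[i, ]) + mk * (s[i] + s0) * dp
    }
  }
  list(dprime = out_d, centroids = out_c)
}

test_that("delta = 0 keeps all genes and reproduces the raw class centroids", {
  toy <- toy_training()
  m <- fit_nsc(toy$x, toy$labels, delta_grid = 0)
  expect_identical(sort(m$selected_genes), sort(rownames(toy$x)))
  for (k in tnbc_subtypes())
    expect_equal(m$shrunken_centroids[, k],
                 rowMeans(toy$x[, toy$labels == k]), tolerance = 1e-12)
})

test_that("full shrinkage selects no genes and predicts from priors alone", {
  toy <- toy_training()
  big <- max(abs(fit_nsc(toy$x, toy$labels, delta_grid = 0)$d)) + 1
  m <- fit_nsc(toy$x, toy$labels, delta_grid = big)
  expect_length(m$selected_genes, 0)
  # all shrunken centroids collapse onto the overall centroid
  expect_equal(m$shrunken_centroids[, "BLIA"], m$shrunken_centroids[, "MES"])
  pred <- predict(m, toy$x)
  expect_length(unique(pred), 1)   # degenerate prior-only classifier
})

test_that("shrunken differences and centroids match the formula oracle", {
  set.seed(7)
  x <- matrix(rnorm(3 * 10, c(5, 8, 6), 1), 3, 10)
  rownames(x) <- c("g1", "g2", "g3")
  colnames(x) <- paste0("s", 1:10)
  labels <- rep(c("A", "B"), each = 5)
  x[1, labels == "B"] <- x[1, labels == "B"] + 2
  for (delta in c(0, 0.4, 1.5)) {
    m <- fit_nsc(x, labels, delta_grid = delta, cv_folds = 2)
    o <- nsc_oracle(x, labels, delta)
    expect_equal(m$dprime, o$dprime, tolerance = 1e-12)
    expect_equal(m$shrunken_centroids, o$centroids, tolerance = 1e-12)
  }
})

test_that("gene sets are nested as the threshold grows", {
  toy <- toy_training(sep = 1.5)
  base <- fit_nsc(toy$x, toy$labels, delta_grid = 0)
  deltas <- seq(0, max(abs(base$d)), length.out = 12)
  sets <- lapply(deltas, function(d)
    fit_nsc(toy$x, toy$labels, delta_grid = d)$selected_genes)
  for (j in 2:length(sets))
    expect_true(all(sets[[j]] %in% sets[[j - 1]]))
})

test_that("at delta = 0 the discriminant reduces to classical nearest centroid", {
  toy <- toy_training()
  m <- fit_nsc(toy$x, toy$labels, delta_grid = 0)
  pred <- predict(m, toy$x)
  # classical nearest centroid in the (s_i + s0)-standardized metric
  denom <- (m$s + m$s0)^2
  nc <- apply(toy$x, 2, function(v) {
    d2 <- vapply(tnbc_subtypes(), function(k)
      sum((v - rowMeans(toy$x[, toy$labels == k]))^2 / denom), 0)
    names(which.min(d2))
  })
  expect_identical(unname(pred), unname(nc))
})

test_that("cross-validation is seed-deterministic and recorded", {
  toy <- toy_training(n_per_class = 8, sep = 1)
  m1 <- fit_nsc(toy$x, toy$labels, seed = 5)
  m2 <- fit_nsc(toy$x, toy$labels, seed = 5)
  expect_identical(m1$cv_table, m2$cv_table)
  expect_identical(m1$delta, m2$delta)
  expect_equal(nrow(m1$cv_table), 30)
})

test_that("training recovers marker genes from a synthetic cohort", {
  # at the CV-selected (parsimonious) threshold the signature keeps a
  # substantial fraction of the true markers; the rare-subtype block can be
  # shrunk hardest because its m_k is largest
  recall <- vapply(1:10, function(s) {
    spec <- cohort_spec(n_samples = 84, n_test = 0, seed = s)
    co <- generate_expression(spec)
    x <- normalize_housekeeping(co$counts)
    m <- fit_nsc(x, co$true_subtype, seed = s)
    for (k in c("BLIA", "BLIS", "LAR"))
      expect_gt(length(intersect(m$selected_genes, co$marker_genes[[k]])), 0)
    length(m$selected_genes) / nrow(x)
  }, 0)
  expect_gt(mean(recall), 0.55)
  expect_gt(min(recall), 0.5)
})

test_that("degenerate training inputs are rejected", {
  toy <- toy_training()
  expect_error(fit_nsc(toy$x, rep("A", ncol(toy$x))), "2 classes")
  labels <- toy$labels; labels[labels == "MES"] <- "BLIA"
  labels[1] <- "MES"
  expect_error(fit_nsc(toy$x, labels), "fewer than 2 samples")
  xna <- toy$x; xna[1, 1] <- NA
  expect_error(fit_nsc(xna, toy$labels), "missing")
})

test_that("quantile centroids match the hand-computable construction", {
  # 4 genes, 2 subtypes, 3 samples each; quantiles of ranks then median
  x <- cbind(a1 = c(1, 2, 3, 4), a2 = c(2, 1, 3, 4), a3 = c(1, 3, 2, 4),
             b1 = c(4, 3, 2, 1), b2 = c(4, 2, 3, 1), b3 = c(3, 4, 2, 1))
  rownames(x) <- paste0("g", 1:4)
  labels <- rep(c("A", "B"), each = 3)
  ctr <- quantile_centroids(x, labels)
  q <- (seq_len(4) - 0.5) / 4   # quantile ladder 0.125 .. 0.875
  # gene g1 in A has ranks (1,2,1) -> quantiles (.125,.375,.125), median .125
  expect_equal(unname(ctr$centroids["A", "g1"]), q[1])
  expect_equal(unname(ctr$centroids["B", "g1"]), median(q[c(4, 4, 3)]))
  # brute-force recomputation of every cell
  for (k in c("A", "B")) for (g in rownames(x)) {
    vals <- apply(x[, labels == k], 2, function(v)
      (rank(v)[g] - 0.5) / length(v))
    expect_equal(unname(ctr$centroids[k, g]), median(vals))
  }
})

test_that("quantile centroids are rank-invariant and handle single samples", {
  toy <- toy_training(n_per_class = 4)
  ctr1 <- quantile_centroids(toy$x, toy$labels)
  shifted <- toy$x
  shifted[, 3] <- shifted[, 3] + 100   # constant shift of one training sample
  expect_equal(quantile_centroids(shifted, toy$labels)$centroids, ctr1$centroids)
  # one sample per subtype: centroid rows equal that sample's quantile vector
  one <- toy$x[, c(1, 5, 9, 13)]
  lab1 <- toy$labels[c(1, 5, 9, 13)]
  ctr <- quantile_centroids(one, lab1)
  for (j in 1:4)
    expect_equal(unname(ctr$centroids[lab1[j], ]),
                 unname((rank(one[, j]) - 0.5) / nrow(one)))
})
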