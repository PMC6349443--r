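nsc_stats <- function(x, labels) {
  classes <- sort(unique(labels))
  n <- ncol(x)
  nk <- table(factor(labels, levels = classes))
  xbar <- rowMeans(x)
  xbar_k <- vapply(classes, function(k)
    rowMeans(x[, labels == k, drop = FALSE]), numeric(nrow(x)))
  ss <- 0
  for (k in classes)
    ss <- ss + rowSums((x[, labels == k, drop = FALSE] - xbar_k[, k])^2)
  s_i <- sqrt(ss / (n - length(classes)))     # pooled within-class SD
  s0 <- stats::median(s_i)
  m_k <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(m_k) <- classes
  d <- sweep(xbar_k - xbar, 1, s_i + s0, `/`)
  d <- sweep(d, 2, m_k, `/`)                  # d_ik
  list(classes = classes, nk = nk, xbar = xbar, xbar_k = xbar_k,
       s = s_i, s0 = s0, m = m_k, d = d)
}

soft_threshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

shrunken_centroids <- function(st, delta) {
  dp <- soft_threshold(st$d, delta)
  ctr <- st$xbar + sweep(sweep(dp, 2, st$m, `*`), 1, st$s + st$s0, `*`)
  list(dprime = dp, centroids = ctr,
       selected = rownames(st$d)[rowSums(dp != 0) > 0])
}

nsc_predict_at <- function(st, delta, newx, priors) {
  sc <- shrunken_centroids(st, delta)
  denom <- (st$s + st$s0)^2
  disc <- vapply(st$classes, function(k) {
    colSums((newx - sc$centroids[, k])^2 / denom) - 2 * log(priors[k])
  }, numeric(ncol(newx)))
  st$classes[max.col(-disc, ties.method = "first")]
}

# deterministic stratified fold assignment
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a nearest-shrunken-centroid (PAM) model
#'
#' Trains the shrunken-centroid classifier used for signature gene
#' selection. For gene i and class k, the standardized centroid difference
#' is `d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0))` with
#' `m_k = sqrt(1/n_k - 1/n)`, `s_i` the pooled within-class standard
#' deviation and `s0` the median of the `s_i`. Differences are soft-
#' thresholded by `delta` (`d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)`),
#' giving shrunken centroids
#' `xbar'_ik = xbar_i + m_k * (s_i + s0) * d'_ik`; genes with all `d'_ik`
#' zero are dropped from the signature. The threshold is chosen by
#' stratified k-fold cross-validation over `delta_grid`, taking the largest
#' delta (fewest genes) attaining the minimum misclassification count.
#'
#' @param x numeric matrix, genes x samples, log2 normalized expression.
#' @param labels class label per sample (>= 2 classes, each with >= 2
#'   samples).
#' @param delta_grid thresholds to evaluate; default 30 values from 0 to
#'   `max |d_ik|`.
#' @param cv_folds number of CV folds (default 10, reduced to the smallest
#'   class size if necessary).
#' @param priors class prior probabilities for the discriminant; default
#'   uniform.
#' @param seed integer seed making the fold assignment deterministic.
#' @return An object of class `nsc_model` with the per-gene statistics,
#'   shrunken differences at the selected threshold, selected gene set and
#'   the CV table.
#' @export
fit_nsc <- function(x, labels, delta_grid = NULL, cv_folds = 10,
                    priors = NULL, seed = 1L) {
  if (anyNA(x)) stopf("expression matrix contains missing values")
  labels <- as.character(labels)
  if (ncol(x) != length(labels)) stopf("labels must match columns of x")
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least 2 classes")
  if (any(tab < 2))
    stopf("class with fewer than 2 samples: %s",
          paste(names(tab)[tab < 2], collapse = ", "))
  st <- nsc_stats(x, labels)
  if (is.null(priors)) priors <- stats::setNames(
    rep(1 / length(st$classes), length(st$classes)), st$classes)
  priors <- priors[st$classes]
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(st$d)), length.out = 30)
  cv_folds <- min(cv_folds, min(tab))

  cv_err <- with_seed(seed, {
    fold <- stratified_folds(labels, cv_folds)
    err <- numeric(length(delta_grid))
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      st_f <- nsc_stats(x[, tr, drop = FALSE], labels[tr])
      for (j in seq_along(delta_grid)) {
        pred <- nsc_predict_at(st_f, delta_grid[j], x[, !tr, drop = FALSE], priors)
        err[j] <- err[j] + sum(pred != labels[!tr])
      }
    }
    err
  })
  best <- max(delta_grid[cv_err == min(cv_err)])   # fewest genes on ties
  sc <- shrunken_centroids(st, best)
  structure(list(
    classes = st$classes, overall_centroid = st$xbar,
    class_centroids = st$xbar_k, s = st$s, s0 = st$s0, m = st$m,
    d = st$d, delta = best, dprime = sc$dprime,
    shrunken_centroids = sc$centroids, selected_genes = sc$selected,
    priors = priors,
    cv_table = data.frame(delta = delta_grid, cv_errors = cv_err)
  ), class = "nsc_model")
}

#' @export
print.nsc_model <- function(x, ...) {
  cat(sprintf("nsc_model: %d classes, delta = %.3f, %d/%d genes selected\n",
              length(x$classes), x$delta, length(x$selected_genes),
              nrow(x$d)))
  invisible(x)
}

#' Predict classes from a fitted NSC model
#'
#' Assigns each sample to the class minimizing the shrunken-centroid
#' discriminant `sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`.
#'
#' @param object an `nsc_model`.
#' @param newx genes x samples matrix covering the model's genes.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.nsc_model <- function(object, newx, ...) {
  newx <- newx[names(object$overall_centroid), , drop = FALSE]
  denom <- (object$s + object$s0)^2
  disc <- vapply(object$classes, function(k) {
    colSums((newx - object$shrunken_centroids[, k])^2 / denom) -
      2 * log(object$priors[k])
  }, numeric(ncol(newx)))
  stats::setNames(object$classes[max.col(-disc, ties.method = "first")],
                  colnames(newx))
}

#' Quantile expression centroids
#'
#' Builds the reference signature shipped with a trained subtype panel.
#' Each training sample's expression over the signature genes is rank
#' transformed within sample (average ranks for ties) and mapped to
#' uniform quantiles `(rank - 0.5) / G`; the centroid of a subtype at a
#' gene is the median of that gene's quantile values over the subtype's
#' samples. The construction is invariant to any strictly increasing
#' per-sample transform of expression, matching the Spearman-correlation
#' classifier it feeds.
#'
#' @param x genes x samples log2 expression matrix.
#' @param labels subtype label per sample; every subtype must have >= 1
#'   sample.
#' @param genes signature genes (subset of `rownames(x)`); default all.
#' @param meta provenance metadata stored in the result.
#' @return A [signature_centroids()] object (subtype x gene).
#' @export
quantile_centroids <- function(x, labels, genes = rownames(x), meta = list()) {
  labels <- as.character(labels)
  if (ncol(x) != length(labels)) stopf("labels must match columns of x")
  absent <- setdiff(genes, rownames(x))
  if (length(absent)) stopf("gene(s) not in x: %s", paste(absent, collapse = ", "))
  classes <- sort(unique(labels[!is.na(labels)]))
  if (length(classes) < 2) stopf("need samples from at least 2 subtypes")
  if (anyNA(labels)) stopf("missing subtype labels")
  q <- apply(x[genes, , drop = FALSE], 2,
             function(v) (rank(v, ties.method = "average") - 0.5) / length(v))
  rownames(q) <- genes
  ctr <- t(vapply(classes, function(k)
    apply(q[, labels == k, drop = FALSE], 1, stats::median), numeric(length(genes))))
  meta$transform <- "within-sample-quantile"
  signature_centroids(ctr, meta = meta)
}
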