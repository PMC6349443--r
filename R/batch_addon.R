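#' Freeze a batch-adjustment reference from training data
#'
#' Stores the per-gene training mean and variance that define the
#' standardization of the addon (frozen ComBat-style) adjustment. These
#' parameters are computed once from the training batch and never updated:
#' any number of new batches can subsequently be mapped onto them with
#' [addon_adjust()] without touching the training data. Genes whose
#' training variance falls below `var_floor` cannot be standardized; they
#' are recorded and later passed through mean-centered onto the training
#' mean.
#'
#' @param x_train genes x samples log2 expression matrix (>= 2 samples).
#' @param var_floor minimum admissible training variance (default 1e-8).
#' @return An object of class `batch_model` with `alpha` (means), `sigma2`
#'   (population variances, denominator n — the pooled-variance convention
#'   of reference-batch adjustment), `genes` and `low_var`.
#' @export
fit_reference <- function(x_train, var_floor = 1e-8) {
  if (ncol(x_train) < 2) stopf("need >= 2 training samples")
  if (is.null(rownames(x_train))) stopf("x_train needs gene rownames")
  alpha <- rowMeans(x_train)
  sigma2 <- rowMeans((x_train - alpha)^2)
  low <- sigma2 < var_floor
  if (all(low))
    stopf("all genes have near-zero training variance; raise var_floor or check input")
  if (any(low))
    warnf("%d gene(s) with training variance < %g will be passed through centered",
          sum(low), var_floor)
  structure(list(alpha = alpha, sigma2 = sigma2, genes = rownames(x_train),
                 low_var = low, n_train = ncol(x_train)),
            class = "batch_model")
}

#' @export
print.batch_model <- function(x, ...) {
  cat(sprintf("batch_model: %d genes frozen from %d training samples (%d low-variance)\n",
              length(x$genes), x$n_train, sum(x$low_var)))
  invisible(x)
}

# ComBat-style iterative EB solution for one batch
eb_solve <- function(z, gamma_hat, delta2_hat, tol = 1e-6, max_iter = 200) {
  n <- ncol(z)
  gamma_bar <- mean(gamma_hat)
  tau2 <- stats::var(gamma_hat)
  m <- mean(delta2_hat); s2 <- stats::var(delta2_hat)
  lambda <- (2 * s2 + m^2) / s2          # inverse-gamma shape hyperprior
  theta <- (m * s2 + m^3) / s2           # inverse-gamma scale hyperprior
  g_old <- gamma_hat; d_old <- delta2_hat
  for (it in seq_len(max_iter)) {
    g_new <- (n * tau2 * gamma_hat + d_old * gamma_bar) / (n * tau2 + d_old)
    ss <- rowSums((z - g_new)^2)
    d_new <- (theta + 0.5 * ss) / (n / 2 + lambda - 1)
    if (max(abs(g_new - g_old) / (abs(g_old) + 1e-12),
            abs(d_new - d_old) / d_old) < tol) {
      g_old <- g_new; d_old <- d_new; break
    }
    g_old <- g_new; d_old <- d_new
  }
  list(gamma_star = g_old, delta2_star = d_old,
       hyper = c(gamma_bar = gamma_bar, tau2 = tau2, lambda = lambda, theta = theta))
}

#' Adjust a new batch onto a frozen reference
#'
#' Addon empirical-Bayes batch adjustment: each test-batch gene is
#' standardized with the *frozen* training mean and variance,
#' `Z_gj = (X_gj - alpha_g) / sigma_g`; the new batch's per-gene location
#' and scale `(gamma_g, delta2_g)` are estimated on Z and shrunk by
#' parametric empirical Bayes (normal prior on location, inverse-gamma on
#' scale, hyperparameters by method of moments across genes); the adjusted
#' values are `X* = sigma_g * (Z - gamma*_g) / sqrt(delta2*_g) + alpha_g`.
#' The training batch is never modified, so prediction rules trained on it
#' transfer to the adjusted data. With `eb = FALSE` the raw moment
#' estimates are used (exact per-gene moment matching, no shrinkage).
#'
#' @param x_test genes x samples log2 expression matrix (>= 3 samples).
#' @param ref a `batch_model` from [fit_reference()].
#' @param eb apply parametric empirical-Bayes shrinkage (default `TRUE`).
#' @return Adjusted matrix over the gene intersection, with attribute
#'   `"batch_params"` (per-gene `gamma_star`, `delta2_star`).
#' @export
addon_adjust <- function(x_test, ref, eb = TRUE) {
  stopifnot(inherits(ref, "batch_model"))
  if (ncol(x_test) < 3) stopf("need >= 3 test samples to estimate batch parameters")
  shared <- intersect(ref$genes, rownames(x_test))
  if (length(shared) == 0) stopf("no genes shared with the reference model")
  lost <- 1 - length(shared) / length(ref$genes)
  if (lost > 0.10)
    warnf("%.0f%% of reference genes missing from test data", 100 * lost)
  x <- x_test[shared, , drop = FALSE]
  alpha <- ref$alpha[shared]; sigma2 <- ref$sigma2[shared]
  low <- ref$low_var[shared]
  ok <- !low
  out <- x
  if (any(ok)) {
    z <- sweep(sweep(x[ok, , drop = FALSE], 1, alpha[ok]), 1, sqrt(sigma2[ok]), `/`)
    gamma_hat <- rowMeans(z)
    delta2_hat <- apply(z, 1, stats::var)
    if (eb && sum(ok) >= 3) {
      sol <- eb_solve(z, gamma_hat, delta2_hat)
    } else {
      sol <- list(gamma_star = gamma_hat, delta2_star = delta2_hat)
    }
    zs <- sweep(sweep(z, 1, sol$gamma_star), 1, sqrt(sol$delta2_star), `/`)
    out[ok, ] <- sweep(sweep(zs, 1, sqrt(sigma2[ok]), `*`), 1, alpha[ok], `+`)
  } else {
    sol <- list(gamma_star = numeric(0), delta2_star = numeric(0))
  }
  if (any(low))  # pass low-variance genes through centered on training mean
    out[low, ] <- x[low, , drop = FALSE] -
      rowMeans(x[low, , drop = FALSE]) + alpha[low]
  gs <- rep(NA_real_, length(shared)); ds <- rep(NA_real_, length(shared))
  gs[ok] <- sol$gamma_star; ds[ok] <- sol$delta2_star
  attr(out, "batch_params") <- data.frame(gene = shared, gamma_star = gs,
                                          delta2_star = ds)
  out
}

#' PCA batch-alignment diagnostic
#'
#' Quantifies batch separation in the first two principal components of
#' the combined (training + test) data, before and after adjustment. The
#' separation statistic is the distance between the two batch centroids in
#' PC1-2 divided by the mean within-batch distance of samples to their own
#' centroid; on batch-shifted data it is expected to drop after
#' adjustment.
#'
#' @param x_train,x_test_pre,x_test_post genes x samples matrices over a
#'   shared gene set (>= 3 samples total per comparison).
#' @return List of class `pca_check`: `sep_pre`, `sep_post`, and the PC1-2
#'   score matrices `scores_pre`, `scores_post` (with a `batch` attribute).
#' @export
pca_check <- function(x_train, x_test_pre, x_test_post) {
  shared <- Reduce(intersect, list(rownames(x_train), rownames(x_test_pre),
                                   rownames(x_test_post)))
  if (length(shared) == 0) stopf("no shared genes")
  sep2 <- function(tr, te) {
    if (ncol(tr) + ncol(te) < 3) stopf("need >= 3 samples")
    m <- cbind(tr[shared, , drop = FALSE], te[shared, , drop = FALSE])
    batch <- rep(c("train", "test"), c(ncol(tr), ncol(te)))
    sc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
    ctr <- rbind(colMeans(sc[batch == "train", , drop = FALSE]),
                 colMeans(sc[batch == "test", , drop = FALSE]))
    between <- sqrt(sum((ctr[1, ] - ctr[2, ])^2))
    within <- mean(sqrt(rowSums((sc - ctr[match(batch, c("train", "test")), ])^2)))
    list(sep = between / within, scores = sc, batch = batch)
  }
  pre <- sep2(x_train, x_test_pre)
  post <- sep2(x_train, x_test_post)
  structure(list(sep_pre = pre$sep, sep_post = post$sep,
                 scores_pre = pre$scores, scores_post = post$scores,
                 batch = pre$batch),
            class = "pca_check")
}

#' @export
print.pca_check <- function(x, ...) {
  cat(sprintf("pca_check: batch separation %.3f (pre) -> %.3f (post)\n",
              x$sep_pre, x$sep_post))
  invisible(x)
}
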