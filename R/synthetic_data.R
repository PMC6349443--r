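#' Specify a synthetic TNBC cohort
#'
#' Bundles all parameters of the synthetic-cohort generator. The defaults
#' emulate the structure of a two-batch nCounter TNBC study: a "training"
#' batch (signature construction) and a "test" batch (new cohort) measured
#' on a 99-probe codeset (77 signature genes, 8 housekeeping genes, positive
#' and negative control probes), with four latent molecular subtypes, a
#' gene-wise additive + multiplicative batch effect on the test batch,
#' subtype-dependent clinical covariates, and exponential survival with
#' subtype-specific hazards.
#'
#' @param n_samples total number of samples across both batches.
#' @param n_test number of samples in the test batch (the remainder form the
#'   training batch). Defaults to half of `n_samples` (rounded up).
#' @param subtype_props named proportions over `c("BLIA","BLIS","LAR","MES")`,
#'   summing to 1. Default: the classified-cohort composition 38/46/25/4
#'   out of 113.
#' @param group_props proportions over the strata labels (default four
#'   race/ethnicity groups, marginals 34/48/12/21 out of 115), summing to 1.
#'   May instead be a `length(groups) x 4` matrix of per-subtype column
#'   distributions (columns in canonical subtype order).
#' @param groups labels of the strata.
#' @param n_signature_genes number of endogenous signature genes; split into
#'   four near-equal marker blocks, one per subtype.
#' @param separation mean log2 up-shift of a subtype's marker genes in
#'   samples of that subtype (non-negative).
#' @param batch_shift list with `delta_mean`, `delta_sd` (gene-wise additive
#'   log2 shift drawn `N(delta_mean, delta_sd)` for test-batch samples) and
#'   `var_fold` (multiplicative inflation of the log-scale noise variance).
#' @param hazard_by_subtype named positive event hazards per month.
#' @param censor_rate positive censoring hazard per month.
#' @param dispersion negative-binomial size parameter of the count noise.
#' @param noise_sd log2-scale biological noise standard deviation.
#' @param deterministic_mix if `TRUE` (default) subtype labels are allocated
#'   by largest-remainder exact proportions within each batch; if `FALSE`
#'   they are drawn multinomially.
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   cohort.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_samples = 199,
                        n_test = NULL,
                        subtype_props = c(BLIA = 38, BLIS = 46, LAR = 25, MES = 4) / 113,
                        group_props = c(White = 34, Hispanic = 48,
                                        AfricanAmerican = 12, Asian = 21) / 115,
                        groups = NULL,
                        n_signature_genes = 77,
                        separation = 2.0,
                        batch_shift = list(delta_mean = 1.5, delta_sd = 0.5, var_fold = 2),
                        hazard_by_subtype = c(BLIA = 0.004, BLIS = 0.010,
                                              LAR = 0.001, MES = 0.008),
                        censor_rate = 0.005,
                        dispersion = 10,
                        noise_sd = 0.5,
                        deterministic_mix = TRUE,
                        seed = 1L) {
  if (length(n_samples) != 1 || n_samples < 0 || n_samples != round(n_samples))
    stopf("n_samples must be a single non-negative integer")
  if (is.null(n_test)) n_test <- ceiling(n_samples / 2)
  if (n_test < 0 || n_test > n_samples)
    stopf("n_test must lie in [0, n_samples]")
  st <- tnbc_subtypes()
  if (length(subtype_props) != 4)
    stopf("subtype_props must have 4 entries (%s)", paste(st, collapse = ", "))
  if (is.null(names(subtype_props))) names(subtype_props) <- st
  subtype_props <- subtype_props[st]
  if (anyNA(subtype_props)) stopf("subtype_props must be named by subtype")
  if (abs(sum(subtype_props) - 1) > 1e-9) stopf("subtype_props must sum to 1")
  if (any(subtype_props < 0)) stopf("subtype_props must be non-negative")

  if (is.matrix(group_props)) {
    if (ncol(group_props) != 4)
      stopf("matrix group_props needs 4 columns (one per subtype)")
    if (is.null(groups)) groups <- rownames(group_props)
    if (any(abs(colSums(group_props) - 1) > 1e-9))
      stopf("each column of group_props must sum to 1")
  } else {
    if (is.null(groups)) groups <- names(group_props)
    if (abs(sum(group_props) - 1) > 1e-9) stopf("group_props must sum to 1")
  }
  if (is.null(groups)) stopf("groups must be named")

  if (separation < 0) stopf("separation must be non-negative")
  if (length(hazard_by_subtype) != 4)
    stopf("hazard_by_subtype needs one rate per subtype")
  if (is.null(names(hazard_by_subtype))) names(hazard_by_subtype) <- st
  hazard_by_subtype <- hazard_by_subtype[st]
  if (anyNA(hazard_by_subtype) || any(hazard_by_subtype <= 0))
    stopf("hazards must be positive and named by subtype")
  if (censor_rate <= 0) stopf("censor_rate must be positive")
  if (dispersion <= 0) stopf("dispersion must be positive")

  structure(list(
    n_samples = as.integer(n_samples), n_test = as.integer(n_test),
    subtype_props = subtype_props, group_props = group_props, groups = groups,
    n_signature_genes = as.integer(n_signature_genes),
    separation = separation, batch_shift = batch_shift,
    hazard_by_subtype = hazard_by_subtype, censor_rate = censor_rate,
    dispersion = dispersion, noise_sd = noise_sd,
    deterministic_mix = isTRUE(deterministic_mix), seed = as.integer(seed)
  ), class = "cohort_spec")
}

# exact largest-remainder allocation of n items to proportions p
largest_remainder <- function(n, p) {
  quota <- n * p
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

draw_labels <- function(n, props, labels, deterministic) {
  if (n == 0) return(character(0))
  if (deterministic) {
    counts <- largest_remainder(n, props)
    sample(rep(labels, counts))
  } else {
    sample(labels, n, replace = TRUE, prob = props)
  }
}

# nCounter-style positive control ladder (counts at nominal spike levels)
POS_LADDER <- c(POS_A = 8192, POS_B = 2048, POS_C = 512,
                POS_D = 128, POS_E = 32, POS_F = 8)
NEG_MEAN <- 2
N_NEG <- 8

#' Generate synthetic expression counts
#'
#' Draws a probes-by-samples integer count matrix with the layout of a
#' targeted nCounter codeset: four blocks of subtype-marker genes (each
#' up-shifted by `separation` log2 units in its own subtype), housekeeping
#' genes independent of subtype, negative-control probes at background and
#' positive-control probes on a fixed ladder. Counts are negative binomial
#' around log-normal per-sample library scaling; test-batch samples receive
#' a gene-wise additive log2 shift plus noise-variance inflation.
#'
#' @param spec a [cohort_spec()].
#' @return A list of class `synthetic_cohort` with elements `counts`
#'   (a [raw_count_matrix()]), `true_subtype`, `batch` (`"train"`/`"test"`),
#'   `marker_genes` (list per subtype), and `spec`.
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  st <- tnbc_subtypes()
  hk <- default_housekeeping()
  g_sig <- spec$n_signature_genes
  sig_ids <- sprintf("SIG%03d", seq_len(g_sig))
  block <- largest_remainder(g_sig, rep(0.25, 4))
  marker <- split(sig_ids, rep(st, block))[st]

  probe_ids <- c(sig_ids, hk, names(POS_LADDER), sprintf("NEG_%s", LETTERS[seq_len(N_NEG)]))
  probe_class <- c(rep("endogenous", g_sig), rep("housekeeping", length(hk)),
                   rep("positive", length(POS_LADDER)), rep("negative", N_NEG))

  n <- spec$n_samples
  sample_ids <- sprintf("S%03d", seq_len(n))
  with_seed(spec$seed, {
    batch <- c(rep("train", n - spec$n_test), rep("test", spec$n_test))
    true_subtype <- c(
      draw_labels(n - spec$n_test, spec$subtype_props, st, spec$deterministic_mix),
      draw_labels(spec$n_test, spec$subtype_props, st, spec$deterministic_mix))

    mu_sig <- stats::runif(g_sig, 6, 10)          # baseline log2 abundance
    mu_hk <- stats::runif(length(hk), 9, 11)
    delta <- stats::rnorm(g_sig, spec$batch_shift$delta_mean, spec$batch_shift$delta_sd)
    libf <- stats::rnorm(n, 0, 0.5)               # log2 library-size factor

    counts <- matrix(0L, nrow = length(probe_ids), ncol = n,
                     dimnames = list(probe_ids, sample_ids))
    if (n > 0) {
      sd_j <- ifelse(batch == "test",
                     spec$noise_sd * sqrt(spec$batch_shift$var_fold), spec$noise_sd)
      # endogenous signature genes
      up <- matrix(0, g_sig, n)
      for (k in st) up[sig_ids %in% marker[[k]], true_subtype == k] <- spec$separation
      shift <- outer(delta, as.numeric(batch == "test"))
      eps <- matrix(stats::rnorm(g_sig * n, 0, rep(sd_j, each = g_sig)), g_sig, n)
      mu <- 2^(mu_sig + up + shift + eps + rep(libf, each = g_sig))
      counts[seq_len(g_sig), ] <- stats::rnbinom(g_sig * n, mu = mu, size = spec$dispersion)
      # housekeeping: subtype-independent
      eps_h <- matrix(stats::rnorm(length(hk) * n, 0, spec$noise_sd), length(hk), n)
      mu_h <- 2^(mu_hk + eps_h + rep(libf, each = length(hk)))
      counts[g_sig + seq_along(hk), ] <-
        stats::rnbinom(length(hk) * n, mu = mu_h, size = spec$dispersion)
      # positive ladder scales with library size; negatives at flat background
      mu_p <- outer(POS_LADDER, 2^libf)
      counts[probe_class == "positive", ] <-
        stats::rnbinom(length(mu_p), mu = mu_p, size = spec$dispersion)
      counts[probe_class == "negative", ] <- stats::rpois(N_NEG * n, NEG_MEAN)
    }
    storage.mode(counts) <- "integer"
    structure(list(
      counts = raw_count_matrix(counts, probe_class),
      true_subtype = stats::setNames(true_subtype, sample_ids),
      batch = stats::setNames(batch, sample_ids),
      marker_genes = marker, spec = spec
    ), class = "synthetic_cohort")
  })
}

# Table-derived covariate distributions (per subtype / per group)
SYN_GRADE2_P <- c(BLIA = 2 / 38, BLIS = 5 / 46, LAR = 10 / 23, MES = 0.05)
SYN_STAGE_P <- rbind(BLIA = c(13, 22, 3) / 38, BLIS = c(12, 31, 3) / 46,
                     LAR = c(6, 11, 8) / 25, MES = c(0.45, 0.45, 0.10))
SYN_NODE_P <- c(BLIA = 10 / 36, BLIS = 5 / 46, LAR = 10 / 24, MES = 1 / 4)
SYN_AGE_MEAN <- c(BLIA = 51, BLIS = 55, LAR = 64, MES = 50)
SYN_RACE_BY_SUBTYPE <- cbind(BLIA = c(10, 14, 5, 9) / 38, BLIS = c(12, 25, 5, 4) / 46,
                             LAR = c(9, 6, 2, 8) / 25, MES = c(2, 2, 0.5, 0.5) / 5)
SYN_FH_BY_GROUP <- c(0.323, 0.375, 0.583, 0.381)
SYN_DETECT_P <- c(lump = 0.68, mammogram = 0.26, other = 0.06)

#' Generate clinical covariates and survival outcomes
#'
#' Adds a clinical table to a synthetic cohort: grade, stage, tumor size,
#' nodal status, age and group membership drawn with subtype-dependent
#' probabilities; event times exponential with the spec's per-subtype
#' hazards and independent exponential censoring; surgery, recurrence,
#' death and last-contact dates emitted consistently with the censoring
#' rules (time unit months, dates ISO-8601).
#'
#' @param cohort a `synthetic_cohort` from [generate_expression()].
#' @param spec the same [cohort_spec()].
#' @return A `clinical_table` data frame, one row per sample.
#' @export
generate_clinical_survival <- function(cohort, spec) {
  if (is.null(cohort$true_subtype)) stopf("cohort lacks true subtype labels")
  ids <- names(cohort$true_subtype)
  n <- length(ids)
  sub <- cohort$true_subtype
  with_seed(spec$seed + 1L, {
    if (is.matrix(spec$group_props)) {
      gp <- spec$group_props
    } else if (identical(spec$groups,
                         c("White", "Hispanic", "AfricanAmerican", "Asian"))) {
      gp <- SYN_RACE_BY_SUBTYPE
      rownames(gp) <- spec$groups
    } else {
      gp <- matrix(spec$group_props, length(spec$groups), 4,
                   dimnames = list(spec$groups, tnbc_subtypes()))
    }
    group <- vapply(sub, function(k) sample(spec$groups, 1, prob = gp[, k]), "")
    age <- pmax(27, round(stats::rnorm(n, SYN_AGE_MEAN[sub], 12)))
    fh_p <- SYN_FH_BY_GROUP[match(group, spec$groups)]
    fh_p[is.na(fh_p)] <- 0.38
    family_history <- ifelse(stats::runif(n) < fh_p, "yes", "no")
    detection <- sample(names(SYN_DETECT_P), n, replace = TRUE, prob = SYN_DETECT_P)
    grade <- ifelse(stats::runif(n) < SYN_GRADE2_P[sub], 2L, 3L)
    stage <- vapply(sub, function(k) sample(1:3, 1, prob = SYN_STAGE_P[k, ]), 0L)
    size_p <- list(`1` = c(0.8, 0.2, 0, 0), `2` = c(0.2, 0.7, 0.1, 0),
                   `3` = c(0, 0.3, 0.5, 0.2))
    tumor_size <- vapply(stage, function(s)
      paste0("T", sample(1:4, 1, prob = size_p[[as.character(s)]])), "")
    node_positive <- ifelse(stats::runif(n) < SYN_NODE_P[sub], "yes", "no")

    h <- spec$hazard_by_subtype[sub]
    recur_t <- stats::rexp(n, 1.5 * h)      # latent recurrence time (months)
    death_t <- stats::rexp(n, h)            # latent death time (months)
    censor_t <- stats::rexp(n, spec$censor_rate)
    from_bc <- recur_t < death_t            # death preceded by recurrence
    died <- death_t <= censor_t
    recurred <- recur_t <= pmin(death_t, censor_t)

    surgery <- as.Date("2000-01-01") +
      sample.int(as.integer(as.Date("2016-07-31") - as.Date("2000-01-01")), n, replace = TRUE)
    to_date <- function(m) surgery + round(m * DAYS_PER_MONTH)
    recurrence_date <- ifelse(recurred, format(to_date(recur_t)), "")
    death_date <- ifelse(died, format(to_date(death_t)), "")
    death_from_bc <- ifelse(died, ifelse(from_bc, "yes", "no"), "")
    last_contact <- format(to_date(pmin(death_t, censor_t)))

    clinical_table(data.frame(
      row.names = NULL,
      sample_id = ids, age_dx = unname(as.numeric(age)), group = unname(group),
      family_history = family_history, detection = detection,
      grade = grade, stage = stage, tumor_size = tumor_size,
      node_positive = node_positive,
      surgery_date = format(surgery), recurrence_date = recurrence_date,
      death_date = death_date, death_from_bc = death_from_bc,
      last_contact_date = last_contact, stringsAsFactors = FALSE))
  })
}

#' Simulate a complete two-batch cohort
#'
#' Convenience wrapper: [generate_expression()] followed by
#' [generate_clinical_survival()].
#'
#' @param spec a [cohort_spec()].
#' @return A `synthetic_cohort` with a `clinical` element added.
#' @export
simulate_cohort <- function(spec) {
  cohort <- generate_expression(spec)
  cohort$clinical <- generate_clinical_survival(cohort, spec)
  cohort
}
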