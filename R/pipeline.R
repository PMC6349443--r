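#' Train a subtype signature from a normalized training batch
#'
#' Convenience composition of the signature-construction stage: fit the
#' nearest-shrunken-centroid model (gene selection), build quantile
#' centroids over the selected genes, and freeze the batch-adjustment
#' reference on the training expression.
#'
#' @param x_train genes x samples log2 normalized training expression.
#' @param labels training subtype labels.
#' @param seed seed for the NSC cross-validation folds.
#' @param ... passed to [fit_nsc()].
#' @return List: `nsc` (the model), `centroids`
#'   ([signature_centroids()] over the selected genes), `reference`
#'   (frozen [fit_reference()] model).
#' @export
train_signature <- function(x_train, labels, seed = 1L, ...) {
  nsc <- fit_nsc(x_train, labels, seed = seed, ...)
  genes <- nsc$selected_genes
  if (length(genes) < 3) {
    warnf("NSC selected %d genes; falling back to all genes", length(genes))
    genes <- rownames(x_train)
  }
  list(nsc = nsc,
       centroids = quantile_centroids(x_train, labels, genes,
                                      meta = list(delta = nsc$delta)),
       reference = fit_reference(x_train))
}

#' Run the pipeline end-to-end on a synthetic cohort
#'
#' Exercises the full analysis chain on generated data with known truth:
#' simulate a two-batch cohort, normalize each batch, train the signature
#' on the training batch, addon-adjust the test batch onto the frozen
#' reference (optionally skipped, for ablation), classify the test batch,
#' and score concordance with the true labels.
#'
#' @param spec a [cohort_spec()].
#' @param skip_adjust bypass the batch adjustment (ablation).
#' @param tau_unclassified,tau_mixed classifier thresholds.
#' @return List: `cohort`, `signature`, `calls` (test batch),
#'   `concordance` (vs true test labels), `accuracy` (fraction of all test
#'   samples whose assigned subtype equals the truth), `pca`
#'   (the [pca_check()] diagnostic; `NULL` when adjustment is skipped).
#' @export
run_synthetic_pipeline <- function(spec, skip_adjust = FALSE,
                                   tau_unclassified = 0.55, tau_mixed = 0.1) {
  cohort <- simulate_cohort(spec)
  tr <- names(cohort$batch)[cohort$batch == "train"]
  te <- names(cohort$batch)[cohort$batch == "test"]
  norm_all <- normalize_housekeeping(cohort$counts)
  x_tr <- norm_all[, tr, drop = FALSE]
  x_te <- norm_all[, te, drop = FALSE]
  sig <- train_signature(x_tr, cohort$true_subtype[tr], seed = spec$seed)
  pca <- NULL
  if (skip_adjust) {
    x_adj <- x_te
  } else {
    x_adj <- addon_adjust(x_te, sig$reference)
    pca <- pca_check(x_tr, x_te, x_adj)
  }
  calls <- classify_cohort(x_adj, sig$centroids, tau_unclassified, tau_mixed)
  conc <- concordance(calls, cohort$true_subtype[te])
  acc <- mean(calls$calls$assigned == cohort$true_subtype[te])
  list(cohort = cohort, signature = sig, calls = calls,
       concordance = conc, accuracy = acc, pca = pca)
}

log_line <- function(con, stage, ...) {
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage = stage),
           list(...))
  writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
}

#' Run the file-based analysis pipeline
#'
#' Orchestrates normalize -> adjust -> classify -> association stats ->
#' survival over files on disk and writes a report bundle (`calls.tsv`,
#' `summary.json`, `tables.json`, `survfit.json`, `log.jsonl`) to
#' `out_dir`. The signature is either trained from a training batch
#' (`train_counts` + `train_labels`) or supplied as a centroid file
#' (`centroids`; batch adjustment is then unavailable and is skipped with
#' a log entry). All decisions (thresholds, gene drops, seeds) are logged
#' as JSON lines. Reruns with the same inputs and seed are byte-identical.
#'
#' @param counts path to the test-cohort raw count TSV.
#' @param clinical optional path to the clinical CSV (enables the stats
#'   and survival stages).
#' @param train_counts,train_labels paths to the training count TSV and a
#'   two-column CSV (`sample_id`, `subtype`).
#' @param centroids path to a centroid TSV (alternative to training).
#' @param out_dir output directory (created if needed).
#' @param tau_unclassified,tau_mixed classifier thresholds.
#' @param pos_norm apply positive-control normalization before the
#'   housekeeping step.
#' @param skip_adjust bypass batch adjustment.
#' @param seed integer seed (cross-validation folds).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(counts, clinical = NULL, train_counts = NULL,
                         train_labels = NULL, centroids = NULL,
                         out_dir = ".", tau_unclassified = 0.55,
                         tau_mixed = 0.1, pos_norm = FALSE,
                         skip_adjust = FALSE, seed = 1L) {
  if (!(tau_unclassified > 0 && tau_unclassified < 1 &&
        tau_mixed > 0 && tau_mixed < 1))
    stopf("thresholds must lie in (0, 1)")
  if (is.null(train_counts) && is.null(centroids))
    stopf("supply either train_counts + train_labels or a centroids file")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(out_dir, "log.jsonl"), open = "wt")
  on.exit(close(con), add = TRUE)
  log_line(con, "config", seed = seed, tau_unclassified = tau_unclassified,
           tau_mixed = tau_mixed, pos_norm = pos_norm,
           skip_adjust = skip_adjust)

  raw <- read_counts(counts)
  qc <- qc_assess(raw)
  x_te <- normalize_housekeeping(raw, pos_norm = pos_norm)
  log_line(con, "normalize", n_samples = ncol(x_te), n_genes = nrow(x_te),
           n_flagged = sum(qc$low_signal | qc$high_background | qc$hk_failure))

  pca <- NULL
  if (!is.null(train_counts)) {
    lab_df <- utils::read.csv(train_labels, stringsAsFactors = FALSE)
    raw_tr <- read_counts(train_counts)
    x_tr <- normalize_housekeeping(raw_tr, pos_norm = pos_norm)
    labels <- stats::setNames(lab_df$subtype, lab_df$sample_id)[colnames(x_tr)]
    sig <- train_signature(x_tr, labels, seed = seed)
    ctr <- sig$centroids
    log_line(con, "train", delta = sig$nsc$delta,
             n_selected = length(sig$nsc$selected_genes))
    if (!skip_adjust) {
      x_te <- addon_adjust(x_te, sig$reference)
      pca <- pca_check(x_tr, normalize_housekeeping(raw, pos_norm = pos_norm), x_te)
      log_line(con, "adjust", sep_pre = pca$sep_pre, sep_post = pca$sep_post)
    } else {
      log_line(con, "adjust", skipped = TRUE)
    }
  } else {
    ctr <- read_centroids(centroids)
    log_line(con, "adjust", skipped = TRUE,
             reason = "no training batch; centroids supplied directly")
  }

  calls <- classify_cohort(x_te, ctr, tau_unclassified, tau_mixed)
  write_calls(calls$calls, file.path(out_dir, "calls.tsv"))
  jsonlite::write_json(calls$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(con, "classify", n = calls$summary$n_samples,
           n_unclassified = calls$summary$n_unclassified,
           n_mixed = calls$summary$n_mixed)

  tables <- NULL; surv <- NULL
  if (!is.null(clinical)) {
    clin <- read_clinical(clinical)
    tables <- association_report(clin, calls)
    jsonlite::write_json(tables, file.path(out_dir, "tables.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(con, "stats", n_tables = length(tables$fisher))
    surv <- survival_report(clin, calls)
    jsonlite::write_json(surv, file.path(out_dir, "survfit.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(con, "survival", n = length(surv$os$km))
  }
  log_line(con, "done")
  invisible(list(qc = qc, expression = x_te, calls = calls, pca = pca,
                 tables = tables, survival = surv))
}

# Fisher tests + enrichment fits for the standard clinical variables
association_report <- function(clin, calls) {
  vars <- c("grade", "node_positive", "stage", "group", "family_history")
  fisher <- list()
  for (v in vars) {
    tab <- tryCatch(build_table(clin, calls, v, "subtype"),
                    error = function(e) NULL)
    if (is.null(tab) || nrow(tab) < 2 || ncol(tab) < 2) next
    res <- tryCatch(fisher_exact_rc(tab), warning = function(w) NULL,
                    error = function(e) NULL)
    if (!is.null(res))
      fisher[[v]] <- list(counts = tab, p_value = res$p_value)
  }
  enrich <- list()
  df <- calls$calls
  sub <- df$assigned[match(clin$sample_id, df$sample_id)]
  keep <- sub %in% tnbc_subtypes()
  for (k in c("BLIS", "LAR")) {
    yes <- tapply(sub[keep] == k, clin$group[keep], sum)
    tot <- tapply(rep(1, sum(keep)), clin$group[keep], sum)
    fit <- tryCatch(fit_group_enrichment(yes, tot - yes),
                    error = function(e) NULL)
    if (!is.null(fit)) enrich[[k]] <- fit
  }
  list(fisher = fisher, enrichment = enrich)
}

# KM + log-rank + Cox (+ Schoenfeld) for OS and RFS by subtype
survival_report <- function(clin, calls) {
  eps <- derive_endpoints(clin)
  df <- calls$calls
  sub <- df$assigned[match(clin$sample_id, df$sample_id)]
  keep <- sub %in% tnbc_subtypes()
  one <- function(time, event) {
    time <- time[keep]; event <- event[keep]; s <- sub[keep]
    km <- lapply(split(seq_along(s), s), function(i) km_fit(time[i], event[i]))
    lr <- tryCatch(logrank_test(time, event, s), error = function(e) NULL)
    cov <- data.frame(subtype = s, age = clin$age_dx[keep],
                      stage = factor(clin$stage[keep]), group = clin$group[keep])
    cx <- tryCatch(cox_fit(time, event, cov,
                           ref_levels = list(subtype = "BLIA")),
                   error = function(e) NULL)
    zph <- if (!is.null(cx)) tryCatch(schoenfeld_check(cx),
                                      error = function(e) NULL) else NULL
    list(km = km, logrank = lr[c("chisq", "df", "p_value")],
         cox = if (!is.null(cx)) cx$table else NULL,
         schoenfeld = if (!is.null(zph)) zph else NULL)
  }
  list(os = one(eps$os_time, eps$os_event),
       rfs = one(eps$rfs_time, eps$rfs_event),
       n_rfs_flagged = sum(eps$rfs_flag))
}

#' Write a self-contained demo workspace
#'
#' Simulates a training batch (n = 84) and a test batch (n = 115) — the
#' sample sizes of the study design the package emulates — and writes
#' them as a ready-to-run workspace: training counts + labels, test
#' counts, clinical table, true test labels, and a README with the
#' commands to reproduce the analysis.
#'
#' @param dir target directory.
#' @param seed integer seed.
#' @return Invisibly, the paths written.
#' @export
make_demo <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  spec <- cohort_spec(n_samples = 199, n_test = 115, seed = seed)
  cohort <- simulate_cohort(spec)
  tr <- names(cohort$batch)[cohort$batch == "train"]
  te <- names(cohort$batch)[cohort$batch == "test"]
  subset_counts <- function(ids) raw_count_matrix(
    cohort$counts$counts[, ids, drop = FALSE], cohort$counts$probe_class)
  paths <- list(
    train_counts = file.path(dir, "train_counts.tsv"),
    train_labels = file.path(dir, "train_labels.csv"),
    test_counts = file.path(dir, "test_counts.tsv"),
    clinical = file.path(dir, "clinical.csv"),
    true_labels = file.path(dir, "test_true_labels.csv"),
    readme = file.path(dir, "README.txt"))
  write_counts(subset_counts(tr), paths$train_counts)
  utils::write.csv(data.frame(sample_id = tr, subtype = cohort$true_subtype[tr]),
                   paths$train_labels, row.names = FALSE, quote = FALSE)
  write_counts(subset_counts(te), paths$test_counts)
  write_clinical(clinical_table(cohort$clinical[cohort$clinical$sample_id %in% te, ]),
                 paths$clinical)
  utils::write.csv(data.frame(sample_id = te, subtype = cohort$true_subtype[te]),
                   paths$true_labels, row.names = FALSE, quote = FALSE)
  writeLines(c(
    "Synthetic TNBC subtyping demo workspace (generated data, known truth).",
    "",
    "Train batch: 84 samples; test batch: 115 samples; 77 signature genes;",
    "a gene-wise batch shift separates the two batches.",
    "",
    "Run from R:",
    "  library(tnbctype)",
    sprintf("  run_pipeline(counts = 'test_counts.tsv', clinical = 'clinical.csv',"),
    sprintf("               train_counts = 'train_counts.tsv',"),
    sprintf("               train_labels = 'train_labels.csv',"),
    sprintf("               out_dir = 'results', seed = %d)", seed),
    "",
    "Compare results/calls.tsv against test_true_labels.csv."),
    paths$readme)
  invisible(paths)
}
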