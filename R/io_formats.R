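PROBE_CLASSES <- c("endogenous", "housekeeping", "positive", "negative")

#' Construct a raw count matrix
#'
#' Container for probes-by-samples nCounter-style raw counts with a probe
#' class annotation (`endogenous`, `housekeeping`, `positive`, `negative`).
#'
#' @param counts non-negative integer matrix, probes in rows (rownames =
#'   probe ids), samples in columns (colnames = sample ids).
#' @param probe_class character vector, one class per probe.
#' @return An object of class `raw_counts`.
#' @export
raw_count_matrix <- function(counts, probe_class) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stopf("counts must have probe ids as rownames")
  if (ncol(counts) > 0 && is.null(colnames(counts)))
    stopf("counts must have sample ids as colnames")
  if (anyDuplicated(rownames(counts)))
    stopf("duplicate probe id: %s",
          rownames(counts)[duplicated(rownames(counts))][1])
  if (anyDuplicated(colnames(counts)))
    stopf("duplicate sample id: %s",
          colnames(counts)[duplicated(colnames(counts))][1])
  if (length(probe_class) != nrow(counts))
    stopf("probe_class length (%d) != number of probes (%d)",
          length(probe_class), nrow(counts))
  bad <- setdiff(unique(probe_class), PROBE_CLASSES)
  if (length(bad)) stopf("unknown probe_class value(s): %s", paste(bad, collapse = ", "))
  if (anyNA(counts) || any(!is.finite(counts)))
    stopf("counts must be finite and non-missing")
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (any(counts != round(counts))) stopf("counts must be integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 probe_class = stats::setNames(as.character(probe_class), rownames(counts))),
            class = "raw_counts")
}

#' @export
print.raw_counts <- function(x, ...) {
  cat(sprintf("raw_counts: %d probes x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$probe_class)),
                            table(x$probe_class)), collapse = ", ")))
  invisible(x)
}

#' Read / write raw counts as TSV
#'
#' The on-disk format is a TSV with columns `probe_id`, `probe_class`, then
#' one column per sample. `dialect = "rcc"` accepts an RCC-like file whose
#' header blocks are skipped and whose `CodeSummary`-style section
#' (`CodeClass,Name,Accession,Count` CSV lines) is parsed; only single-lane
#' files are supported in that dialect.
#'
#' @param path file path.
#' @param dialect `"tsv"` (default) or `"rcc"`.
#' @return [read_counts()] returns a `raw_counts` object.
#' @export
read_counts <- function(path, dialect = c("tsv", "rcc")) {
  dialect <- match.arg(dialect)
  if (dialect == "rcc") return(read_counts_rcc(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!all(c("probe_id", "probe_class") %in% names(df)))
    stopf("counts file must have probe_id and probe_class columns")
  samp <- names(df)[!names(df) %in% c("probe_id", "probe_class")]
  if (anyDuplicated(samp))
    stopf("duplicate sample column: %s", samp[duplicated(samp)][1])
  m <- as.matrix(df[, samp, drop = FALSE])
  rownames(m) <- df$probe_id
  raw_count_matrix(m, df$probe_class)
}

read_counts_rcc <- function(path) {
  lines <- readLines(path)
  in_code <- FALSE
  rows <- list()
  for (ln in lines) {
    if (grepl("^<CodeSummary>", ln)) { in_code <- TRUE; next }
    if (grepl("^</CodeSummary>", ln)) break
    if (in_code) rows[[length(rows) + 1L]] <- strsplit(ln, ",")[[1]]
  }
  if (length(rows) < 2) stopf("no CodeSummary section found in %s", path)
  hdr <- tolower(rows[[1]])
  body <- do.call(rbind, rows[-1])
  colnames(body) <- hdr
  cls_map <- c(endogenous = "endogenous", housekeeping = "housekeeping",
               positive = "positive", negative = "negative")
  cls <- cls_map[tolower(body[, "codeclass"])]
  if (anyNA(cls)) stopf("unknown CodeClass in RCC file")
  m <- matrix(as.integer(body[, "count"]), ncol = 1,
              dimnames = list(body[, "name"],
                              sub("\\.[^.]*$", "", basename(path))))
  raw_count_matrix(m, unname(cls))
}

#' @rdname read_counts
#' @param x a `raw_counts` object.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "raw_counts"))
  df <- data.frame(probe_id = rownames(x$counts),
                   probe_class = unname(x$probe_class),
                   x$counts, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a signature centroid object
#'
#' Subtype-by-gene reference centroid matrix used for Spearman-correlation
#' subtype calling. Subtypes are stored in canonical order
#' (BLIA, BLIS, LAR, MES) regardless of input order.
#'
#' @param centroids numeric matrix, subtypes in rows, genes in columns.
#' @param meta optional named list of provenance metadata (training-set id,
#'   transform tag, ...).
#' @return An object of class `signature_centroids`.
#' @export
signature_centroids <- function(centroids, meta = list()) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stopf("need at least 2 subtypes")
  if (is.null(rownames(centroids)) || is.null(colnames(centroids)))
    stopf("centroids need subtype rownames and gene colnames")
  if (anyDuplicated(colnames(centroids))) stopf("duplicate gene ids in centroids")
  if (anyNA(centroids) || any(!is.finite(centroids)))
    stopf("centroids must not contain missing values")
  known <- intersect(tnbc_subtypes(), rownames(centroids))
  if (length(known) == nrow(centroids))
    centroids <- centroids[known, , drop = FALSE]
  structure(list(centroids = centroids, subtypes = rownames(centroids),
                 genes = colnames(centroids), meta = meta),
            class = "signature_centroids")
}

#' @export
print.signature_centroids <- function(x, ...) {
  cat(sprintf("signature_centroids: %d subtypes (%s) x %d genes\n",
              length(x$subtypes), paste(x$subtypes, collapse = ", "),
              length(x$genes)))
  invisible(x)
}

#' Read / write signature centroids as TSV
#'
#' On-disk format: first column `gene`, one column per subtype. Round-trips
#' losslessly at 12 significant digits; subtype columns are normalized to
#' canonical order on read.
#'
#' @param path file path.
#' @export
read_centroids <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stopf("first column of a centroid file must be 'gene'")
  m <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(m) <- df$gene
  missing <- setdiff(tnbc_subtypes(), rownames(m))
  if (length(missing) && nrow(m) < 2)
    stopf("missing subtype column(s): %s", paste(missing, collapse = ", "))
  signature_centroids(m)
}

#' @rdname read_centroids
#' @param x a `signature_centroids` object.
#' @export
write_centroids <- function(x, path) {
  stopifnot(inherits(x, "signature_centroids"))
  df <- data.frame(gene = x$genes,
                   signif(t(x$centroids), 12), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

CLINICAL_COLS <- c("sample_id", "age_dx", "group", "family_history", "detection",
                   "grade", "stage", "tumor_size", "node_positive",
                   "surgery_date", "recurrence_date", "death_date",
                   "death_from_bc", "last_contact_date")

#' Construct / validate a clinical table
#'
#' Per-sample clinical covariates plus the dates from which overall and
#' recurrence-free survival are derived. Validation enforces unique sample
#' ids, positive ages, and date ordering (surgery <= recurrence <= death,
#' surgery <= last contact). Missing values are empty strings (dates,
#' yes/no fields) or `NA` (grade).
#'
#' @param df data frame with the columns listed in Details.
#' @return The validated data frame with class `clinical_table`.
#' @export
clinical_table <- function(df) {
  missing <- setdiff(CLINICAL_COLS, names(df))
  if (length(missing)) stopf("clinical table missing column(s): %s",
                             paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stopf("duplicate sample_id: %s", df$sample_id[duplicated(df$sample_id)][1])
  if (any(!is.na(df$age_dx) & df$age_dx <= 0)) stopf("ages must be positive")
  as_d <- function(x) as.Date(ifelse(is.na(x) | x == "", NA, x))
  surg <- as_d(df$surgery_date); rec <- as_d(df$recurrence_date)
  dth <- as_d(df$death_date); lc <- as_d(df$last_contact_date)
  bad <- which((!is.na(rec) & rec < surg) |
               (!is.na(dth) & !is.na(rec) & dth < rec) |
               (!is.na(dth) & dth < surg) |
               (!is.na(lc) & lc < surg))
  if (length(bad))
    stopf("date order violated for sample(s): %s",
          paste(df$sample_id[bad], collapse = ", "))
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Read / write a clinical table as CSV
#'
#' CSV with ISO-8601 dates; missing values are empty cells. Validated via
#' [clinical_table()] on read.
#'
#' @param path file path.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  df$age_dx <- as.numeric(df$age_dx)
  df$grade <- suppressWarnings(as.integer(df$grade))
  df$stage <- as.integer(df$stage)
  clinical_table(df)
}

#' @rdname read_clinical
#' @param x a `clinical_table`.
#' @export
write_clinical <- function(x, path) {
  stopifnot(inherits(x, "clinical_table"))
  out <- as.data.frame(x)
  out[is.na(out)] <- ""
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a subtype call report
#'
#' TSV with one row per sample: the four Spearman correlations (at 12
#' significant digits), assigned subtype, unclassified and mixed flags,
#' top-two gap and mixed pair.
#'
#' @param calls the `calls` data frame from [classify_cohort()].
#' @param path file path.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  for (cc in grep("^rho_", names(out), value = TRUE))
    out[[cc]] <- signif(out[[cc]], 12)
  out$gap <- signif(out$gap, 12)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    colClasses = c(sample_id = "character"))
}
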