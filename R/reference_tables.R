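#' Published cohort summary counts
#'
#' Loads the cross-tabulated clinical counts of the 115-patient TNBC study
#' the package's statistics module is validated against: clinical variables
#' by race/ethnicity (the full cohort) and by molecular subtype (the 113
#' classified cases), plus the per-group subtype yes/no counts used by the
#' deviation-coded enrichment model. These are summary tables, not
#' individual-level data; they serve as worked inputs for
#' [fisher_exact_rc()] and [fit_group_enrichment()].
#'
#' @return List with `by_group` and `by_subtype` (named lists of integer
#'   matrices, one per clinical variable, levels x groups/subtypes) and
#'   `enrichment` (data frame of per-group LAR/BLIS yes/no counts).
#' @export
reference_tables <- function() {
  load_one <- function(file) {
    df <- utils::read.delim(system.file("extdata", file, package = "tnbctype",
                                        mustWork = TRUE),
                            check.names = FALSE, stringsAsFactors = FALSE)
    lapply(split(df, df$variable), function(d) {
      m <- as.matrix(d[, -(1:2)])
      rownames(m) <- d$level
      storage.mode(m) <- "integer"
      m
    })
  }
  enr <- utils::read.csv(system.file("extdata", "subtype_enrichment_counts.csv",
                                     package = "tnbctype", mustWork = TRUE),
                         stringsAsFactors = FALSE)
  list(by_group = load_one("cohort_counts_by_group.tsv"),
       by_subtype = load_one("cohort_counts_by_subtype.tsv"),
       enrichment = enr)
}
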