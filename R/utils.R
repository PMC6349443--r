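#' Canonical subtype order
#'
#' The four TNBC molecular subtypes in the fixed order used throughout the
#' package: basal-like immune-activated (BLIA), basal-like immunosuppressed
#' (BLIS), luminal androgen receptor (LAR), mesenchymal (MES). Ties and
#' column orderings are always resolved against this order.
#'
#' @return Character vector of length 4.
#' @export
tnbc_subtypes <- function() c("BLIA", "BLIS", "LAR", "MES")

#' Default housekeeping genes
#'
#' The eight housekeeping genes of the PAM50/Prosigna panel used for
#' nCounter normalization.
#'
#' @return Character vector of length 8.
#' @export
default_housekeeping <- function() {
  c("ACTB", "GUSB", "MRPL19", "PSMC4", "PUM1", "RPLP0", "SF3A1", "TFRC")
}

# geometric mean of strictly positive values
geomean <- function(x) exp(mean(log(x)))

# days per month used for all date -> month conversions
DAYS_PER_MONTH <- 30.4375

months_between <- function(from, to) {
  as.numeric(difftime(as.Date(to), as.Date(from), units = "days")) / DAYS_PER_MONTH
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
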