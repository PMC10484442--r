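#' @importFrom rlang .data abort warn %||%
#' @importFrom stats glm binomial plogis qlogis rbinom rnorm rlnorm rpois runif
#'   median quantile sd coef vcov pnorm qnorm setNames update
#' @importFrom utils head tail
NULL

.onLoad <- function(libname, pkgname) {
  # block samplers for logistic likelihoods; absence is tolerated (base module
  # samples the same model, only more slowly)
  tryCatch(rjags::load.module("glm", quiet = TRUE), error = function(e) NULL)
  invisible()
}

MONOTHERAPY <- "MONOTHERAPY"

#' Round a dose value for change comparison
#'
#' Dosage values are human-entered decimals; two ADDs are considered equal when
#' they agree after rounding to 6 significant digits, so floating-point noise
#' cannot create spurious "changes".
#'
#' @param x numeric vector of dose values.
#' @return `x` rounded to 6 significant digits.
#' @export
add_round <- function(x) signif(x, 6)

# minutes per unit
MIN_PER_HOUR <- 60
MIN_PER_DAY <- 1440

# stable per-stage seed derivation (kept below 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483587L)
}

# merge a set of [start, end) intervals: overlapping or abutting intervals
# chain into one; returns tibble(start, end) sorted
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(tibble::tibble(start = numeric(0), end = numeric(0)))
  }
  o <- order(start, end)
  start <- start[o]
  end <- end[o]
  ms <- start[1]
  me <- end[1]
  out_s <- numeric(0)
  out_e <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms)
      out_e <- c(out_e, me)
      ms <- start[i]
      me <- end[i]
    }
  }
  tibble::tibble(start = c(out_s, ms), end = c(out_e, me))
}

# do [s1,e1) and [s2,e2) intersect?
intervals_overlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

stop_data <- function(msg) abort(msg, class = "dosepair_data_error")
stop_config <- function(msg) abort(msg, class = "dosepair_config_error")
stop_contract <- function(msg) abort(msg, class = "dosepair_contract_error")
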