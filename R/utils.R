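#' @keywords internal
"_PACKAGE"

# Simulation calendar: month 0 = January 2020.
.SIM_ORIGIN <- as.Date("2020-01-01")

#' Convert calendar dates to simulation month indices
#'
#' Month 0 is January 2020; indices increase by one per calendar month, so
#' December 2020 is month 11 and December 2034 is month 179.
#'
#' @param dates a `Date` vector.
#' @return integer vector of month indices (may be negative for dates before
#'   January 2020).
#' @export
month_index <- function(dates) {
  stopifnot(inherits(dates, "Date"))
  lt <- as.POSIXlt(dates)
  12L * (lt$year + 1900L - 2020L) + lt$mon
}

#' Convert month indices back to (first-of-month) dates
#' @param m integer month indices (0 = January 2020).
#' @return `Date` vector.
#' @export
month_date <- function(m) {
  yr <- 2020L + m %/% 12L
  mo <- m %% 12L + 1L
  as.Date(sprintf("%d-%02d-01", yr, mo))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

# Deterministic per-iteration seeds below 2^31, independent of batch order.
iteration_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}
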