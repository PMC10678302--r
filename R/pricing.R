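# QALY-anchored launch pricing.  Launch price = price-per-QALY rate times
# the therapy's expected incremental QALYs, with the rate calibrated by
# least squares against the list prices of therapies already on the U.S.
# market.

#' Default calibration points: U.S.-launched rare-disease gene therapies
#'
#' The two gene therapies priced in the U.S. market as of January 2020:
#' onasemnogene abeparvovec (spinal muscular atrophy type 1, $2.1M per
#' patient, 20.56 incremental QALYs) and voretigene neparvovec (RPE65
#' retinal disease, $425k per eye, 4.63 incremental QALYs).
#'
#' @return data frame with columns `therapy_name`, `delta_qaly`,
#'   `list_price`, `class`.
#' @export
default_calibration_points <- function() {
  path <- system.file("extdata", "calibration_points.csv",
                      package = "gtbudget")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default price-per-QALY model
#'
#' $101,663 per incremental QALY for rare diseases (calibrated on the two
#' launched rare-disease gene therapies) and $40,797 for other diseases
#' (cancer and general; calibrated on launched CAR-T therapies, taken as a
#' fixed rate because the CAR-T QALY inputs are not public).
#'
#' @param rare,other USD per incremental QALY.
#' @return a `gt_price_model` list.
#' @export
price_model <- function(rare = 101663, other = 40797) {
  if (rare <= 0 || other <= 0) stop_arg("price rates must be positive")
  structure(list(rare = rare, other = other), class = "gt_price_model")
}

check_points <- function(points) {
  if (is.null(points) || nrow(points) == 0) {
    stop_arg("need at least one calibration point")
  }
  if (any(points$delta_qaly <= 0)) stop_arg("delta_qaly must be positive")
  if (any(points$list_price <= 0)) stop_arg("list_price must be positive")
  points
}

#' Calibrate the price per incremental QALY by least squares
#'
#' Finds the scalar rate `p` minimising `sum((p * q_i - c_i)^2)` over the
#' calibration points `(q_i, c_i)`; the closed form is
#' `sum(q_i * c_i) / sum(q_i^2)` (a regression through the origin).
#'
#' @param points data frame with columns `delta_qaly` and `list_price`.
#' @return USD per incremental QALY.
#' @export
calibrate_price_per_qaly <- function(points) {
  check_points(points)
  sum(points$delta_qaly * points$list_price) / sum(points$delta_qaly^2)
}

#' Total squared pricing error at a given rate
#'
#' `sum((p * q_i - c_i)^2)` in squared USD.  The sum (not the mean) is the
#' reported default; `mean = TRUE` divides by the number of points.
#'
#' @inheritParams calibrate_price_per_qaly
#' @param p price per incremental QALY (USD).
#' @param mean return the mean instead of the sum.
#' @return squared-USD error.
#' @export
fit_sse <- function(points, p, mean = FALSE) {
  check_points(points)
  sq <- (p * points$delta_qaly - points$list_price)^2
  if (mean) base::mean(sq) else sum(sq)
}

#' Total absolute percentage pricing error at a given rate
#'
#' `sum(|p * q_i - c_i| / c_i) * 100` in percent.  The sum (not the mean)
#' is the reported default; `mean = TRUE` divides by the number of points.
#'
#' @inheritParams fit_sse
#' @return percent error.
#' @export
fit_sum_ape <- function(points, p, mean = FALSE) {
  check_points(points)
  ape <- abs(p * points$delta_qaly - points$list_price) /
    points$list_price * 100
  if (mean) base::mean(ape) else sum(ape)
}

#' Launch price of a therapy from its expected incremental QALYs
#'
#' Price = price-per-QALY rate x incremental QALYs, with the rare-disease
#' rate for the `rare` category and the other rate for cancer and general
#' diseases.
#'
#' @param delta_qaly expected incremental QALYs per treated patient (> 0).
#' @param model a `gt_price_model`.
#' @param category disease category (`"rare"`, `"cancer"`, `"general"`).
#' @return price in USD.
#' @export
price_of_therapy <- function(delta_qaly, model = price_model(),
                             category = "rare") {
  if (any(delta_qaly <= 0)) stop_arg("delta_qaly must be positive")
  rate <- ifelse(category == "rare", model$rare, model$other)
  rate * delta_qaly
}
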