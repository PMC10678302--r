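# Epidemiological and uptake mathematics.
#
# A disease's patient pool has two parts: the prevalent stock at approval
# (existing patients), which seeks treatment at an exponentially decaying
# rate with a fixed half-life, and the incident flow (new patients), treated
# on diagnosis.  Both are scaled by a ramp-shaped market-penetration curve.

#' Steady-state prevalence from incidence and k-year survival
#'
#' At steady state, `k*i` new patients arrive over `k` years while
#' `j*(1-p)` die, so the constant patient stock is `j = k*i / (1-p)`.
#'
#' @param incidence_i new patients per year (>= 0).
#' @param survival_p proportion alive after `survival_k` years, in `[0,1)`.
#' @param survival_k survival horizon in years (> 0).
#' @return prevalence in persons.
#' @export
steady_state_prevalence <- function(incidence_i, survival_p, survival_k) {
  if (any(incidence_i < 0)) stop_arg("incidence must be >= 0")
  if (any(survival_p < 0 | survival_p >= 1)) {
    stop_arg("survival_p must be in [0, 1): an immortal cohort has no ",
             "steady state")
  }
  if (any(survival_k <= 0)) stop_arg("survival_k must be > 0")
  survival_k * incidence_i / (1 - survival_p)
}

#' Steady-state incidence from prevalence (inverse conversion)
#' @param prevalence_j prevalent patients (>= 0).
#' @inheritParams steady_state_prevalence
#' @return incidence in persons/year.
#' @export
steady_state_incidence <- function(prevalence_j, survival_p, survival_k) {
  if (any(prevalence_j < 0)) stop_arg("prevalence must be >= 0")
  if (any(survival_p < 0 | survival_p >= 1)) {
    stop_arg("survival_p must be in [0, 1)")
  }
  if (any(survival_k <= 0)) stop_arg("survival_k must be > 0")
  prevalence_j * (1 - survival_p) / survival_k
}

#' Fraction of the pre-approval patient stock seeking treatment in a window
#'
#' The prevalent stock declines exponentially with half-life `lambda`
#' (months); the proportion of the original stock seeking treatment between
#' `t` and `t + delta` months after approval is
#' `2^(-t/lambda) - 2^(-(t+delta)/lambda)`.  Window fractions over a
#' partition of `[0, T)` telescope to `1 - 2^(-T/lambda)`.
#'
#' @param t_months months since approval (>= 0).
#' @param delta_months window length in months (> 0).
#' @param half_life_lambda half-life in months (> 0).
#' @return proportion in (0, 1).
#' @export
existing_fraction <- function(t_months, delta_months, half_life_lambda) {
  if (any(t_months < 0)) stop_arg("t_months must be >= 0")
  if (any(delta_months <= 0)) stop_arg("delta_months must be > 0")
  if (any(half_life_lambda <= 0)) stop_arg("half_life_lambda must be > 0")
  2^(-t_months / half_life_lambda) -
    2^(-(t_months + delta_months) / half_life_lambda)
}

#' Half-life implied by a first-year uptake fraction
#'
#' Solves `1 - 2^(-12/lambda) = f` for `lambda` (months):
#' `lambda = 12*log(2) / (-log(1 - f))`.  A first-year fraction of 25%
#' gives 28.91 months; 50% gives exactly 12 months.
#'
#' @param first_year_fraction proportion of the existing stock seeking
#'   treatment in the first 12 months, in (0, 1).
#' @return half-life in months.
#' @export
half_life_from_first_year <- function(first_year_fraction) {
  if (any(first_year_fraction <= 0 | first_year_fraction >= 1)) {
    stop_arg("first_year_fraction must be in (0, 1)")
  }
  12 * log(2) / (-log(1 - first_year_fraction))
}

#' Market-penetration ramp
#'
#' The adoption curve used across the pharmaceutical industry: penetration
#' rises linearly from 0 to a plateau `theta_max` over `t_max` months and
#' stays there.
#'
#' @param t_months months since approval (>= 0).
#' @param theta_max plateau penetration, in (0, 1].
#' @param t_max months to reach the plateau (> 0).
#' @return penetration proportion.
#' @export
penetration <- function(t_months, theta_max, t_max) {
  if (any(t_max <= 0)) stop_arg("t_max must be > 0")
  if (any(t_months < 0)) stop_arg("t_months must be >= 0")
  pmin(t_months / t_max, 1) * theta_max
}

.RAMP_MEANS <- list(
  rare    = c(theta_max = 0.40, t_max = 6),
  general = c(theta_max = 0.01, t_max = 60),
  cancer  = c(theta_max = 0.10, t_max = 12)
)

#' Draw ramp parameters for a disease category
#'
#' Category means encode the adoption assumptions: rare diseases ramp to a
#' 40% plateau in 6 months (small, motivated populations with few
#' alternatives); general chronic diseases to 1% in 5 years (existing
#' standards of care, cautious uptake); cancers fall in between at 10% in
#' 12 months.  Draws are normal with standard deviation
#' `dispersion * mean`, clipped to the valid ranges (`theta_max` to (0,1],
#' `t_max` to > 0); `dispersion = 0` returns the means exactly.
#'
#' @param category one of `"rare"`, `"general"`, `"cancer"`.
#' @param dispersion relative spread (sd/mean), in `[0, 1)`; default 0.10.
#' @param n number of draws.
#' @return list with numeric vectors `theta_max` and `t_max`.
#' @export
draw_ramp_params <- function(category, dispersion = 0.10, n = 1) {
  mu <- .RAMP_MEANS[[category]]
  if (is.null(mu)) stop_arg("unknown category: ", category)
  if (dispersion < 0 || dispersion >= 1) {
    stop_arg("dispersion must be in [0, 1)")
  }
  if (dispersion == 0) {
    return(list(theta_max = rep(mu[["theta_max"]], n),
                t_max = rep(mu[["t_max"]], n)))
  }
  eps <- .Machine$double.eps
  theta <- stats::rnorm(n, mu[["theta_max"]], dispersion * mu[["theta_max"]])
  tmax <- stats::rnorm(n, mu[["t_max"]], dispersion * mu[["t_max"]])
  list(theta_max = pmin(pmax(theta, eps), 1),
       t_max = pmax(tmax, eps))
}

#' Patients treated in a month after approval
#'
#' Monthly treated count
#' `rho(t) * eligible * [new_rate + E(t, 1, lambda) * existing_stock0]`,
#' where `rho` is the penetration ramp and `E` the existing-stock window
#' fraction.  The existing-stock term uses the closed-form window fraction
#' of the original stock, so cumulative treated existing patients can never
#' exceed `existing_stock0 * theta_max * eligible_fraction`.
#'
#' @param t_months months since approval (vectorised, >= 0).
#' @param new_patients_rate newly diagnosed patients per month (>= 0).
#' @param existing_stock0 prevalent patients at approval (>= 0).
#' @param theta_max,t_max ramp parameters (see [penetration()]).
#' @param half_life_lambda existing-stock half-life in months.
#' @param eligible_fraction proportion of the population eligible, (0, 1].
#' @return list with numeric vectors `new`, `existing`, `total` (persons
#'   treated in each month).
#' @export
patients_treated <- function(t_months, new_patients_rate, existing_stock0,
                             theta_max, t_max, half_life_lambda,
                             eligible_fraction = 1) {
  if (new_patients_rate < 0 || existing_stock0 < 0) {
    stop_arg("patient rates must be >= 0")
  }
  rho <- penetration(t_months, theta_max, t_max)
  ef <- existing_fraction(t_months, 1, half_life_lambda)
  new <- rho * eligible_fraction * new_patients_rate
  existing <- rho * eligible_fraction * ef * existing_stock0
  list(new = new, existing = existing, total = new + existing)
}

#' Fill missing incidence or prevalence by steady-state conversion
#'
#' @param registry a `gt_registry`.
#' @return registry with both `incidence_i` and `prevalence_j` populated.
#' @export
complete_epidemiology <- function(registry) {
  d <- registry$diseases
  need_j <- is.na(d$prevalence_j)
  need_i <- is.na(d$incidence_i)
  if (any(need_j)) {
    d$prevalence_j[need_j] <- steady_state_prevalence(
      d$incidence_i[need_j], d$survival_p[need_j], d$survival_k[need_j])
  }
  if (any(need_i)) {
    d$incidence_i[need_i] <- steady_state_incidence(
      d$prevalence_j[need_i], d$survival_p[need_i], d$survival_k[need_i])
  }
  registry$diseases <- d
  registry
}
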