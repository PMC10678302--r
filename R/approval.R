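# Approval simulation: which diseases obtain an approved gene therapy and
# when.  A development program succeeds with its therapeutic area's
# phase-3-to-approval probability; program successes are correlated across
# the pipeline through a Gaussian copula (platform technologies such as
# AAV delivery and CAR-T make program fates far from independent).  A
# disease is approved when at least one of its programs succeeds.

#' Default phase-3-to-approval probabilities of success by therapeutic area
#'
#' Historical phase-3-to-approval rates by therapeutic area from large-scale
#' analyses of drug-development programs (2000-2020).
#'
#' @return named numeric vector of probabilities.
#' @export
default_pos_table <- function() {
  c("Autoimmune/Inflammation" = 0.485,
    "Cardiovascular"          = 0.501,
    "CNS"                     = 0.370,
    "Metabolic/Endocrinology" = 0.457,
    "Oncology"                = 0.285,
    "Ophthalmology"           = 0.459)
}

#' Default regulatory timing model
#'
#' Two sequential lags follow the end of a disease's last trial: BLA
#' preparation and FDA review, each a symmetric triangular number of days
#' on `[0, 365]` with mode (= median) 182.5.
#'
#' @param bla_prep,fda_review length-3 numeric `c(min, mode, max)` in days.
#' @return a `gt_timing` list.
#' @export
timing_model <- function(bla_prep = c(0, 182.5, 365),
                         fda_review = c(0, 182.5, 365)) {
  stopifnot(length(bla_prep) == 3, length(fda_review) == 3,
            !is.unsorted(bla_prep), !is.unsorted(fda_review))
  structure(list(bla_prep = bla_prep, fda_review = fda_review),
            class = "gt_timing")
}

#' Draw from a triangular distribution
#'
#' Inverse-CDF sampling from the triangular distribution on
#' `[min, max]` with the given mode.
#'
#' @param n number of draws.
#' @param min,mode,max distribution support and mode.
#' @return numeric vector in `[min, max]`.
#' @export
rtriangular <- function(n, min = 0, mode = 182.5, max = 365) {
  u <- stats::runif(n)
  if (max == min) return(rep(min, n))  # degenerate: fixed lag
  fc <- (mode - min) / (max - min)
  ifelse(u < fc,
         min + sqrt(u * (max - min) * (mode - min)),
         max - sqrt((1 - u) * (max - min) * (max - mode)))
}

#' Fit a gamma distribution to completed-trial durations
#'
#' Maximum-likelihood gamma fit (in days) to `end_date - start_date` over
#' trials with both dates declared; used to impute missing end dates.
#'
#' @param trials trials data frame (see [new_registry()]).
#' @return list with `shape`, `rate` and the number of durations used,
#'   class `gt_gamma`.
#' @export
fit_duration_gamma <- function(trials) {
  ok <- !is.na(trials$end_date) & !is.na(trials$start_date)
  dur <- as.numeric(trials$end_date[ok] - trials$start_date[ok])
  dur <- dur[dur > 0]
  if (length(dur) < 2) {
    stop_arg("need at least 2 completed trials with positive duration ",
             "to fit the duration distribution")
  }
  m <- mean(dur); v <- stats::var(dur)
  if (v == 0) {
    stop_arg("degenerate durations (all equal: ", m, " days); the ",
             "maximum-likelihood gamma shape diverges")
  }
  fit <- fitdistrplus::fitdist(dur, "gamma",
                               start = list(shape = m^2 / v, rate = m / v))
  structure(list(shape = unname(fit$estimate["shape"]),
                 rate = unname(fit$estimate["rate"]),
                 n = length(dur)),
            class = "gt_gamma")
}

#' Impute missing trial end dates from the fitted duration distribution
#'
#' Each trial with a missing end date receives `start_date` plus a random
#' gamma-distributed duration (rounded to whole days).
#'
#' @param registry a `gt_registry`.
#' @param duration_gamma a `gt_gamma` fit (or any list with `shape`, `rate`).
#' @return registry with every trial dated.
#' @export
impute_end_dates <- function(registry, duration_gamma) {
  t <- registry$trials
  miss <- is.na(t$end_date)
  if (any(miss)) {
    draw <- stats::rgamma(sum(miss), shape = duration_gamma$shape,
                          rate = duration_gamma$rate)
    t$end_date[miss] <- t$start_date[miss] + round(draw)
  }
  registry$trials <- t
  registry
}

#' Simulate correlated program successes through a Gaussian copula
#'
#' Latent standard normals with exchangeable pairwise correlation `rho`
#' across all program pairs (`z_i = sqrt(rho) * z0 + sqrt(1-rho) * e_i`);
#' program `i` succeeds iff `z_i < qnorm(PoS_i)`.  The copula changes joint
#' behaviour only: each program's marginal success probability equals its
#' area's phase-3-to-approval probability for every `rho`.
#'
#' @param programs data frame with columns `program_id` and
#'   `therapeutic_area`, one row per development program.
#' @param pos_table named probabilities by therapeutic area (see
#'   [default_pos_table()]); values may be scaled by sensitivity analyses
#'   and are capped at 1.
#' @param correlation pairwise latent correlation, in `[0, 1]`.
#' @return named logical vector of success flags by `program_id`.
#' @export
simulate_successes <- function(programs, pos_table = default_pos_table(),
                               correlation = 0.9) {
  if (correlation < 0 || correlation > 1) {
    stop_arg("correlation must be in [0, 1]")
  }
  pos <- pos_table[programs$therapeutic_area]
  if (anyNA(pos)) {
    stop_arg("no probability of success for area(s): ",
             paste(unique(programs$therapeutic_area[is.na(pos)]),
                   collapse = ", "))
  }
  pos <- pmin(pos, 1)
  m <- nrow(programs)
  z0 <- stats::rnorm(1)
  z <- sqrt(correlation) * z0 + sqrt(1 - correlation) * stats::rnorm(m)
  stats::setNames(z < stats::qnorm(pos), programs$program_id)
}

#' Determine per-disease approval outcomes and dates
#'
#' A disease is approved iff any of its development programs succeeds, with
#' two overriding rules applied first: diseases with a previously approved
#' therapy are approved as of 2020-12-31 regardless of flags, and diseases
#' whose last trial ended before the staleness cutoff (default 2017-01-01)
#' with no launch observed are treated as failed.  The approval date of a
#' newly approved disease is the end of its last trial plus a BLA
#' preparation lag plus an FDA review lag (each triangular, see
#' [timing_model()]), converted to a simulation month index and clamped at
#' the simulation start (January 2020).
#'
#' @param registry a `gt_registry` with all end dates present (see
#'   [impute_end_dates()]).
#' @param success_flags named logical by `program_id` from
#'   [simulate_successes()].
#' @param timing a `gt_timing` model.
#' @param stale_cutoff date before which a last-trial end means failure.
#' @param lag_scale length-2 multiplier on the two lag draws (sensitivity
#'   analyses).
#' @return data frame with `disease_id`, `approved`, `approval_month`
#'   (month index, `NA` when not approved).
#' @export
disease_approval <- function(registry, success_flags,
                             timing = timing_model(),
                             stale_cutoff = as.Date("2017-01-01"),
                             lag_scale = c(1, 1)) {
  d <- registry$diseases
  t <- registry$trials
  stopifnot(!anyNA(t$end_date))
  n <- nrow(d)
  last_end <- as.Date(vapply(
    d$disease_id,
    function(id) max(t$end_date[t$disease_id == id]),
    numeric(1)), origin = "1970-01-01")
  prog_success <- vapply(d$disease_id, function(id) {
    ids <- unique(t$program_id[t$disease_id == id])
    any(success_flags[ids])
  }, logical(1))

  # Lags are drawn for every disease so the random stream does not depend
  # on the success pattern (keeps sensitivity runs seed-comparable).
  lag1 <- rtriangular(n, timing$bla_prep[1], timing$bla_prep[2],
                      timing$bla_prep[3]) * lag_scale[1]
  lag2 <- rtriangular(n, timing$fda_review[1], timing$fda_review[2],
                      timing$fda_review[3]) * lag_scale[2]

  approved <- d$prior_approval | (prog_success & last_end >= stale_cutoff)
  month <- rep(NA_integer_, n)
  prior <- d$prior_approval
  month[prior] <- month_index(as.Date("2020-12-31"))
  new_appr <- approved & !prior
  if (any(new_appr)) {
    appr_date <- last_end[new_appr] + round(lag1[new_appr] + lag2[new_appr])
    month[new_appr] <- pmax(month_index(appr_date), 0L)
  }
  data.frame(disease_id = d$disease_id, approved = approved,
             approval_month = month, stringsAsFactors = FALSE)
}
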