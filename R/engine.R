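# Monte Carlo driver.  Each iteration simulates correlated program
# successes, imputes missing trial end dates, converts trial ends plus
# regulatory lags into approval months, draws adoption-ramp parameters, and
# accumulates monthly treated patients, spending (price from the
# QALY-anchored model) and QALYs gained.  Iterations are reduced to
# elementwise means and percentile bands.

.PERTURB_VARS <- c("theta_max", "t_max", "delta_qaly", "price_per_qaly",
                   "pos_3a", "new_patients", "existing_patients",
                   "days_p3_to_bla", "days_bla_to_approval")

#' Simulation configuration
#'
#' @param horizon_months simulation horizon; default 180 (January 2020
#'   through December 2034).
#' @param n_iterations Monte Carlo iterations (default 1000; increase for
#'   production runs — percentile bands stabilise slowly).
#' @param seed master seed; per-iteration substreams are derived from it so
#'   results do not depend on batching.
#' @param correlation latent pairwise correlation between development
#'   programs (default 0.9).
#' @param discount_rate_annual annual discount rate for present-value
#'   spending (default 0.03, compounded monthly).
#' @param first_year_fraction fraction of the prevalent stock seeking
#'   treatment in the first year after approval (default 0.25; fixes the
#'   depletion half-life at 28.91 months).
#' @param dispersion relative spread of the adoption-ramp draws (sd/mean,
#'   default 0.10).
#' @param percentiles lower/upper band probabilities (default 5th/95th).
#' @param pos_table probabilities of success by therapeutic area.
#' @param price_mod a `gt_price_model`.
#' @param timing a `gt_timing` regulatory lag model.
#' @param stale_cutoff diseases whose last trial ended before this date
#'   without a launch are treated as failed (default 2017-01-01).
#' @param perturb named multipliers for one-way sensitivity analyses over
#'   `theta_max`, `t_max`, `delta_qaly`, `price_per_qaly`, `pos_3a`,
#'   `new_patients`, `existing_patients`, `days_p3_to_bla`,
#'   `days_bla_to_approval`; all default 1.
#' @return a `gt_config` list.
#' @export
simulation_config <- function(horizon_months = 180,
                              n_iterations = 1000,
                              seed = 1,
                              correlation = 0.9,
                              discount_rate_annual = 0.03,
                              first_year_fraction = 0.25,
                              dispersion = 0.10,
                              percentiles = c(0.05, 0.95),
                              pos_table = default_pos_table(),
                              price_mod = price_model(),
                              timing = timing_model(),
                              stale_cutoff = as.Date("2017-01-01"),
                              perturb = list()) {
  if (horizon_months <= 0) stop_arg("horizon_months must be > 0")
  if (n_iterations < 1) stop_arg("n_iterations must be >= 1")
  if (correlation < 0 || correlation > 1) {
    stop_arg("correlation must be in [0, 1]")
  }
  if (discount_rate_annual < 0) stop_arg("discount rate must be >= 0")
  unknown <- setdiff(names(perturb), .PERTURB_VARS)
  if (length(unknown)) {
    stop_arg("unknown perturbation variable(s): ",
             paste(unknown, collapse = ", "))
  }
  pert <- stats::setNames(rep(1, length(.PERTURB_VARS)), .PERTURB_VARS)
  pert[names(perturb)] <- unlist(perturb)
  structure(list(
    horizon_months = as.integer(horizon_months),
    n_iterations = as.integer(n_iterations),
    seed = seed,
    correlation = correlation,
    discount_rate_annual = discount_rate_annual,
    first_year_fraction = first_year_fraction,
    half_life = half_life_from_first_year(first_year_fraction),
    dispersion = dispersion,
    percentiles = percentiles,
    pos_table = pos_table,
    price_mod = price_mod,
    timing = timing,
    stale_cutoff = stale_cutoff,
    perturb = as.list(pert)
  ), class = "gt_config")
}

#' Discount a monthly series to present value
#'
#' Value at month `m` is multiplied by
#' `(1 + annual_rate)^(-(m - reference_month)/12)`.
#'
#' @param series numeric monthly series (month 0 first).
#' @param annual_rate annual discount rate (>= 0).
#' @param reference_month month index of the present (default 0, January
#'   2020).
#' @return discounted series.
#' @export
discount <- function(series, annual_rate, reference_month = 0) {
  if (annual_rate < 0) stop_arg("annual_rate must be >= 0")
  m <- seq_along(series) - 1
  series * (1 + annual_rate)^(-(m - reference_month) / 12)
}

#' Split spending across Medicare, Medicaid and private payers
#'
#' All elderly patients are assumed covered by Medicare; two in five minors
#' and one in seven adults by Medicaid; the remainder by private plans.
#' Components always sum to the total.
#'
#' @param total_spending total spending (USD).
#' @param age_shares named proportions over `minor`, `adult`, `elderly`
#'   summing to 1.
#' @return named numeric: `Medicare`, `Medicaid`, `private`.
#' @export
payer_decomposition <- function(total_spending, age_shares) {
  sh <- age_shares[c("minor", "adult", "elderly")]
  if (anyNA(sh) || abs(sum(sh) - 1) > 1e-9) {
    stop_arg("age_shares must cover minor/adult/elderly and sum to 1")
  }
  medicare <- sh[["elderly"]] * total_spending
  medicaid <- (2 / 5 * sh[["minor"]] + 1 / 7 * sh[["adult"]]) * total_spending
  c(Medicare = medicare, Medicaid = medicaid,
    private = total_spending - medicare - medicaid)
}

prepare_registry <- function(registry) {
  validate_registry(registry)
  registry <- adjust_overlaps(registry)
  complete_epidemiology(registry)
}

# One Monte Carlo iteration on a prepared registry (overlaps adjusted,
# epidemiology completed).  Random draws are made for every disease in a
# fixed order regardless of outcomes, so perturbed reruns under the same
# seed reuse identical random streams (common random numbers).
#' Run a single simulation iteration
#'
#' Lower-level entry point used by [run_monte_carlo()]; see that function
#' for the model.  The registry must already be prepared
#' (overlap-adjusted, epidemiology completed); missing end dates are
#' imputed here from `duration_gamma`.
#'
#' @param registry a prepared `gt_registry`.
#' @param config a `gt_config`.
#' @param duration_gamma a `gt_gamma` duration fit, or `NULL` when no end
#'   dates are missing.
#' @return list of monthly vectors/matrices: `approvals_cum`, `pat_new`,
#'   `pat_existing`, `pat_cat` (by category), `sp_new`, `sp_existing`,
#'   `sp_cat`, `sp_age` (by age group), `qalys`.
#' @export
run_iteration <- function(registry, config, duration_gamma = NULL) {
  d <- registry$diseases
  H <- config$horizon_months
  pert <- config$perturb
  n <- nrow(d)

  programs <- unique(registry$trials[, c("program_id", "disease_id")])
  programs$therapeutic_area <-
    d$therapeutic_area[match(programs$disease_id, d$disease_id)]
  succ <- simulate_successes(
    programs,
    pos_table = config$pos_table * pert$pos_3a,
    correlation = config$correlation)
  if (anyNA(registry$trials$end_date)) {
    registry <- impute_end_dates(registry, duration_gamma)
  }
  appr <- disease_approval(
    registry, succ, timing = config$timing,
    stale_cutoff = config$stale_cutoff,
    lag_scale = c(pert$days_p3_to_bla, pert$days_bla_to_approval))
  ramp <- list(
    rare = draw_ramp_params("rare", config$dispersion, n),
    general = draw_ramp_params("general", config$dispersion, n),
    cancer = draw_ramp_params("cancer", config$dispersion, n))

  pat_new <- pat_existing <- qalys <- numeric(H)
  sp_new <- sp_existing <- numeric(H)
  pat_cat <- sp_cat <- matrix(0, H, 3,
                              dimnames = list(NULL, .CATEGORIES))
  sp_age <- matrix(0, H, 3, dimnames = list(NULL,
                                            c("minor", "adult", "elderly")))
  active <- which(appr$approved & appr$approval_month < H)
  for (k in active) {
    a <- appr$approval_month[k]
    t_rel <- 0:(H - a - 1)
    cat_k <- d$category[k]
    theta <- min(ramp[[cat_k]]$theta_max[k] * pert$theta_max, 1)
    tmax <- ramp[[cat_k]]$t_max[k] * pert$t_max
    pt <- patients_treated(
      t_rel,
      new_patients_rate = d$incidence_i[k] / 12 * pert$new_patients,
      existing_stock0 = d$prevalence_j[k] * pert$existing_patients,
      theta_max = theta, t_max = tmax,
      half_life_lambda = config$half_life,
      eligible_fraction = d$eligible_fraction[k])
    price <- price_of_therapy(d$delta_qaly[k] * pert$delta_qaly,
                              model = price_model(
                                rare = config$price_mod$rare *
                                  pert$price_per_qaly,
                                other = config$price_mod$other *
                                  pert$price_per_qaly),
                              category = cat_k)
    idx <- (a + 1):H
    pat_new[idx] <- pat_new[idx] + pt$new
    pat_existing[idx] <- pat_existing[idx] + pt$existing
    pat_cat[idx, cat_k] <- pat_cat[idx, cat_k] + pt$total
    sp_d <- pt$total * price
    sp_new[idx] <- sp_new[idx] + pt$new * price
    sp_existing[idx] <- sp_existing[idx] + pt$existing * price
    sp_cat[idx, cat_k] <- sp_cat[idx, cat_k] + sp_d
    mix <- as.numeric(d[k, c("age_minor", "age_adult", "age_elderly")])
    sp_age[idx, ] <- sp_age[idx, ] + outer(sp_d, mix)
    qalys[idx] <- qalys[idx] +
      pt$total * d$delta_qaly[k] * pert$delta_qaly
  }
  months <- appr$approval_month[appr$approved & appr$approval_month < H]
  approvals_cum <- cumsum(tabulate(months + 1L, H))
  list(approvals_cum = approvals_cum,
       pat_new = pat_new, pat_existing = pat_existing, pat_cat = pat_cat,
       sp_new = sp_new, sp_existing = sp_existing, sp_cat = sp_cat,
       sp_age = sp_age, qalys = qalys)
}

summarize_matrix <- function(M, probs) {
  qs <- apply(M, 2, stats::quantile, probs = probs, names = FALSE)
  list(mean = colMeans(M), lower = qs[1, ], upper = qs[2, ])
}

#' Run the budget-impact Monte Carlo simulation
#'
#' For each iteration: simulate correlated program successes (Gaussian
#' copula at the configured correlation, marginals from the
#' phase-3-to-approval table), impute missing trial end dates from the
#' fitted gamma duration distribution, convert trial ends plus BLA and
#' review lags to approval months, and for each approved disease accrue
#' monthly treated patients (ramp penetration times new-patient flow plus
#' depleting existing stock), spending (patients times the QALY-anchored
#' price) and QALYs.  Iterations are reduced to elementwise means and
#' percentile bands; annual totals and a payer decomposition are derived
#' from the spending series.
#'
#' @param registry a `gt_registry`.
#' @param config a `gt_config` from [simulation_config()].
#' @return a `gt_result` list: `monthly` (per-metric mean/lower/upper
#'   series), `annual` (spending by calendar year), `payer`, `age_shares`,
#'   `cumulative` (nominal and discounted spending, patients, QALYs,
#'   approvals), `peak` (month and value of mean monthly spending), and
#'   the `config` used.
#' @export
run_monte_carlo <- function(registry, config = simulation_config()) {
  registry <- prepare_registry(registry)
  H <- config$horizon_months
  n_it <- config$n_iterations
  needs_gamma <- anyNA(registry$trials$end_date)
  duration_gamma <- if (needs_gamma) fit_duration_gamma(registry$trials)

  keys <- c("approvals_cum", "pat_total", "pat_new", "pat_existing",
            "pat_cancer", "pat_rare", "pat_general",
            "sp_total", "sp_new", "sp_existing",
            "sp_cancer", "sp_rare", "sp_general", "qalys")
  M <- lapply(stats::setNames(keys, keys), function(.) matrix(0, n_it, H))
  age_cum <- matrix(0, n_it, 3,
                    dimnames = list(NULL, c("minor", "adult", "elderly")))
  seeds <- iteration_seeds(config$seed, n_it)
  for (i in seq_len(n_it)) {
    set.seed(seeds[i])
    it <- run_iteration(registry, config, duration_gamma)
    M$approvals_cum[i, ] <- it$approvals_cum
    M$pat_new[i, ] <- it$pat_new
    M$pat_existing[i, ] <- it$pat_existing
    M$pat_total[i, ] <- it$pat_new + it$pat_existing
    M$sp_new[i, ] <- it$sp_new
    M$sp_existing[i, ] <- it$sp_existing
    M$sp_total[i, ] <- it$sp_new + it$sp_existing
    for (cat in .CATEGORIES) {
      M[[paste0("pat_", cat)]][i, ] <- it$pat_cat[, cat]
      M[[paste0("sp_", cat)]][i, ] <- it$sp_cat[, cat]
    }
    M$qalys[i, ] <- it$qalys
    age_cum[i, ] <- colSums(it$sp_age)
  }

  monthly <- lapply(M, summarize_matrix, probs = config$percentiles)
  disc <- discount(rep(1, H), config$discount_rate_annual)
  cum_nominal <- rowSums(M$sp_total)
  cum_discounted <- as.numeric(M$sp_total %*% disc)
  years <- 2020L + (seq_len(H) - 1L) %/% 12L
  annual_mat <- t(rowsum(t(M$sp_total), years))
  ann_q <- apply(annual_mat, 2, stats::quantile,
                 probs = config$percentiles, names = FALSE)
  annual <- data.frame(year = as.integer(colnames(annual_mat)),
                       mean = colMeans(annual_mat),
                       lower = ann_q[1, ], upper = ann_q[2, ],
                       row.names = NULL)

  total_age <- colMeans(age_cum)
  age_shares <- if (sum(total_age) > 0) total_age / sum(total_age) else
    stats::setNames(rep(NA_real_, 3), colnames(age_cum))
  avg_annual <- mean(cum_nominal) / (H / 12)
  payer <- if (all(!is.na(age_shares))) {
    payer_decomposition(avg_annual, age_shares)
  } else {
    c(Medicare = 0, Medicaid = 0, private = 0)
  }

  structure(list(
    monthly = monthly,
    annual = annual,
    payer = payer,
    age_shares = age_shares,
    cumulative = list(
      spending_nominal = stats::setNames(
        c(mean(cum_nominal),
          stats::quantile(cum_nominal, config$percentiles, names = FALSE)),
        c("mean", "lower", "upper")),
      spending_discounted = stats::setNames(
        c(mean(cum_discounted),
          stats::quantile(cum_discounted, config$percentiles,
                          names = FALSE)),
        c("mean", "lower", "upper")),
      patients = mean(rowSums(M$pat_total)),
      qalys = mean(rowSums(M$qalys)),
      approvals = mean(M$approvals_cum[, H])
    ),
    peak = list(month = which.max(monthly$sp_total$mean) - 1L,
                value = max(monthly$sp_total$mean)),
    config = config
  ), class = "gt_result")
}

#' @export
print.gt_result <- function(x, ...) {
  cum <- x$cumulative
  cat(sprintf(
    paste0("<gt_result> %d iterations, %d months\n",
           "  mean approvals by horizon end : %.2f\n",
           "  mean cumulative patients      : %s\n",
           "  mean cumulative spending      : $%.3g (discounted $%.3g)\n",
           "  peak mean monthly spending    : $%.3g in %s\n"),
    x$config$n_iterations, x$config$horizon_months,
    cum$approvals, format(round(cum$patients), big.mark = ","),
    cum$spending_nominal[["mean"]], cum$spending_discounted[["mean"]],
    x$peak$value, format(month_date(x$peak$month), "%B %Y")))
  cat("  payer split: ",
      paste(sprintf("%s $%.3g", names(x$payer), x$payer), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
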