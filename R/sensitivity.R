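# One-way (tornado) sensitivity analysis, correlation and first-year-uptake
# sweeps, and a Poisson pipeline-extension scenario.  All reruns share the
# baseline's random seeds (common random numbers), so reported deltas
# reflect the perturbation rather than Monte Carlo noise.

#' Tornado (one-way) sensitivity analysis
#'
#' Reruns the Monte Carlo with each input scaled up and down by
#' `perturbation` (default +/-20%), one variable at a time, under the
#' baseline seeds.  Reported metrics: percent change in peak mean monthly
#' spending, in cumulative nominal spending and in cumulative discounted
#' spending, plus the shift (months) of the peak-spending month.  Peak
#' months are the argmax of the mean monthly spending series, ties broken
#' toward the earlier month.
#'
#' @param registry a `gt_registry`.
#' @param config baseline `gt_config`.
#' @param variables subset of the nine supported variables (default all):
#'   `theta_max`, `t_max`, `delta_qaly`, `price_per_qaly`, `pos_3a`,
#'   `new_patients`, `existing_patients`, `days_p3_to_bla`,
#'   `days_bla_to_approval`.
#' @param perturbation relative perturbation (default 0.20).
#' @return data frame with columns `variable`, `direction`, `metric`,
#'   `percent_change`, `peak_shift_months`.
#' @export
tornado <- function(registry, config = simulation_config(),
                    variables = .PERTURB_VARS, perturbation = 0.20) {
  unknown <- setdiff(variables, .PERTURB_VARS)
  if (length(unknown)) {
    stop_arg("unknown tornado variable(s): ", paste(unknown, collapse = ", "))
  }
  registry <- prepare_registry(registry)
  base <- run_monte_carlo(registry, config)
  base_metrics <- c(
    peak_monthly_spending = base$peak$value,
    cumulative_spending_nominal =
      base$cumulative$spending_nominal[["mean"]],
    cumulative_spending_discounted =
      base$cumulative$spending_discounted[["mean"]])
  rows <- list()
  for (v in variables) {
    for (dir in c("up", "down")) {
      f <- 1 + if (dir == "up") perturbation else -perturbation
      cfg <- config
      cfg$perturb[[v]] <- cfg$perturb[[v]] * f
      res <- run_monte_carlo(registry, cfg)
      metrics <- c(
        peak_monthly_spending = res$peak$value,
        cumulative_spending_nominal =
          res$cumulative$spending_nominal[["mean"]],
        cumulative_spending_discounted =
          res$cumulative$spending_discounted[["mean"]])
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, direction = dir, metric = names(metrics),
        percent_change = 100 * (metrics / base_metrics - 1),
        peak_shift_months = res$peak$month - base$peak$month,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Sweep the between-program correlation
#'
#' One Monte Carlo per correlation value, sharing the baseline seeds.
#' Mean spending is nonincreasing in the correlation: positive dependence
#' between programs lowers the probability that at least one program for a
#' disease succeeds, while leaving each program's marginal success
#' probability unchanged.
#'
#' @param registry a `gt_registry`.
#' @param config a `gt_config`.
#' @param rho_values correlations to evaluate, each in `[0, 1]`.
#' @return data frame with `rho`, `cumulative_spending_discounted`,
#'   `mean_approvals`.
#' @export
correlation_sweep <- function(registry, config = simulation_config(),
                              rho_values = c(0, 0.9, 1)) {
  if (any(rho_values < 0 | rho_values > 1)) {
    stop_arg("correlations must be in [0, 1]")
  }
  registry <- prepare_registry(registry)
  rows <- lapply(rho_values, function(rho) {
    cfg <- config
    cfg$correlation <- rho
    res <- run_monte_carlo(registry, cfg)
    data.frame(rho = rho,
               cumulative_spending_discounted =
                 res$cumulative$spending_discounted[["mean"]],
               mean_approvals = res$cumulative$approvals)
  })
  do.call(rbind, rows)
}

#' Sweep the first-year uptake fraction of the existing patient stock
#'
#' For each fraction the depletion half-life is recomputed via
#' [half_life_from_first_year()] and the Monte Carlo rerun under baseline
#' seeds.  Spending is reported relative to the 25% baseline: slower
#' depletion pushes treatment of the prevalent stock beyond the simulation
#' horizon and lowers in-horizon spending.
#'
#' @param registry a `gt_registry`.
#' @param config a `gt_config`.
#' @param fractions first-year fractions to evaluate, each in (0, 1).
#' @param baseline_fraction reference fraction (default 0.25).
#' @return data frame with `first_year_fraction`, `half_life_months`,
#'   `cumulative_spending_discounted`, `percent_change_vs_baseline`.
#' @export
uptake_sweep <- function(registry, config = simulation_config(),
                         fractions = c(0.05, 0.25, 0.5, 0.9),
                         baseline_fraction = 0.25) {
  if (any(fractions <= 0 | fractions >= 1)) {
    stop_arg("fractions must be in (0, 1)")
  }
  registry <- prepare_registry(registry)
  run_at <- function(f) {
    cfg <- config
    cfg$first_year_fraction <- f
    cfg$half_life <- half_life_from_first_year(f)
    run_monte_carlo(registry, cfg)$cumulative$spending_discounted[["mean"]]
  }
  base <- run_at(baseline_fraction)
  vals <- vapply(fractions, run_at, numeric(1))
  data.frame(first_year_fraction = fractions,
             half_life_months = half_life_from_first_year(fractions),
             cumulative_spending_discounted = vals,
             percent_change_vs_baseline = 100 * (vals / base - 1))
}

#' Fit a linear trend to program starts per year
#'
#' Ordinary least squares of the number of development programs initiated
#' per year against the calendar year; the extrapolated line, truncated at
#' zero, is the annual arrival rate for the pipeline-extension scenario.
#'
#' @param program_start_years integer vector: the start year of each
#'   program (one entry per program).
#' @return a `gt_pipeline_trend` list with `intercept`, `slope`, and
#'   `rate(year)` giving the truncated extrapolated rate.
#' @export
fit_pipeline_trend <- function(program_start_years) {
  years <- sort(unique(program_start_years))
  if (length(years) < 2) stop_arg("need program starts in >= 2 distinct years")
  counts <- as.numeric(table(factor(program_start_years, levels = years)))
  fit <- stats::lm(counts ~ years)
  co <- stats::coef(fit)
  structure(list(
    intercept = unname(co[1]), slope = unname(co[2]),
    rate = function(year) pmax(0, unname(co[1]) + unname(co[2]) * year)
  ), class = "gt_pipeline_trend")
}

#' Simulate new programs entering the pipeline as a Poisson process
#'
#' Arrivals within each calendar year follow a Poisson process with that
#' year's extrapolated rate `kappa` (exponential inter-arrival times with
#' density `kappa * exp(-kappa * t)`).  Each arrival becomes a new disease
#' whose category is drawn from the registry's empirical category mix and
#' whose epidemiology, QALY gain and age mix are copied from a randomly
#' chosen registry disease of that category, with a single new program
#' whose trial starts at the arrival date (end date left missing, to be
#' imputed like any other).
#'
#' @param trend a `gt_pipeline_trend`.
#' @param registry baseline `gt_registry` providing empirical
#'   distributions.
#' @param years calendar years over which arrivals occur (default
#'   2020:2034).
#' @return a `gt_registry` containing the baseline plus the new synthetic
#'   programs (identical to the baseline when all rates are zero).
#' @export
simulate_pipeline_entry <- function(trend, registry, years = 2020:2034) {
  d <- registry$diseases
  new_d <- list(); new_t <- list()
  idx <- 0
  for (y in years) {
    kappa <- trend$rate(y)
    if (kappa <= 0) next
    t_frac <- stats::rexp(1, kappa)
    while (t_frac < 1) {
      idx <- idx + 1
      cat_i <- sample(d$category, 1)
      src <- d[sample(which(d$category == cat_i), 1), ]
      nd <- src
      nd$disease_id <- sprintf("PIPE%03d", idx)
      nd$name <- sprintf("pipeline %s disease %d", cat_i, idx)
      nd$prior_approval <- FALSE
      nd$parent_disease_id <- NA_character_
      start <- as.Date(sprintf("%d-01-01", y)) + round(365 * t_frac)
      nt <- data.frame(
        trial_id = sprintf("PIPET%03d", idx),
        disease_id = nd$disease_id,
        program_id = sprintf("%s-P1", nd$disease_id),
        phase = "3",
        start_date = start,
        end_date = as.Date(NA),
        stringsAsFactors = FALSE)
      new_d[[idx]] <- nd
      new_t[[idx]] <- nt
      t_frac <- t_frac + stats::rexp(1, kappa)
    }
  }
  if (idx == 0) return(registry)
  out <- new_registry(rbind(d, do.call(rbind, new_d)),
                      rbind(registry$trials, do.call(rbind, new_t)))
  # carry over the adjustment flag so nested-pair counts are not
  # subtracted a second time downstream
  attr(out, "overlap_adjusted") <- attr(registry, "overlap_adjusted")
  out
}

#' Pipeline-extension scenario
#'
#' Fits the program-arrival trend from the registry's own trial start
#' years, simulates new program arrivals over the horizon, and runs the
#' Monte Carlo on the augmented registry.  With a zero arrival rate the
#' result is identical to the baseline under the same seeds.
#'
#' @param registry baseline `gt_registry`.
#' @param config a `gt_config`.
#' @param trend optional `gt_pipeline_trend`; fitted from the registry's
#'   program start years when omitted.
#' @param entry_seed seed for the arrival draws (default `config$seed`).
#' @return list with `trend`, the augmented `registry`, the baseline and
#'   extended `gt_result`s.
#' @export
pipeline_scenario <- function(registry, config = simulation_config(),
                              trend = NULL, entry_seed = NULL) {
  registry <- prepare_registry(registry)
  if (is.null(trend)) {
    tr <- registry$trials
    first_start <- tapply(as.integer(format(tr$start_date, "%Y")),
                          tr$program_id, min)
    trend <- fit_pipeline_trend(as.integer(first_start))
  }
  set.seed(entry_seed %||% config$seed)
  augmented <- simulate_pipeline_entry(trend, registry)
  list(trend = trend,
       registry = augmented,
       baseline = run_monte_carlo(registry, config),
       extended = run_monte_carlo(augmented, config))
}
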