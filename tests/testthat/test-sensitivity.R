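# Small registries and iteration counts: all reruns share seeds, so the
# deltas below are driven by the perturbations, not Monte Carlo noise.

sens_registry <- function() {
  reg <- toy_registry(4, programs_each = 2, category = "rare",
                      area = "Metabolic/Endocrinology",
                      incidence = 240, prevalence = 2000)
  reg$diseases$category[3:4] <- "cancer"
  reg$diseases$therapeutic_area[3:4] <- "Oncology"
  # varied durations so the duration distribution is fittable
  reg$trials$end_date <- reg$trials$end_date +
    seq(0, by = 75, length.out = nrow(reg$trials))
  reg
}

test_that("a zero perturbation reproduces the baseline exactly", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 20, seed = 1)
  tab <- tornado(reg, cfg, variables = "price_per_qaly", perturbation = 0)
  expect_equal(tab$percent_change, rep(0, 6))
  expect_equal(tab$peak_shift_months, rep(0L, 6))
})

test_that("price-per-QALY and QALY-gain tornadoes are exactly linear", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 25, seed = 2)
  tab <- tornado(reg, cfg, variables = c("price_per_qaly", "delta_qaly"))
  up <- tab[tab$direction == "up", ]
  down <- tab[tab$direction == "down", ]
  expect_equal(up$percent_change, rep(20, 6), tolerance = 1e-9)
  expect_equal(down$percent_change, rep(-20, 6), tolerance = 1e-9)
  expect_true(all(tab$peak_shift_months == 0L))
})

test_that("longer regulatory lags shift spending out of the horizon", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 25, seed = 3)
  tab <- tornado(reg, cfg, variables = c("days_p3_to_bla",
                                         "days_bla_to_approval"))
  cum <- tab[tab$metric == "cumulative_spending_nominal", ]
  expect_true(all(cum$percent_change[cum$direction == "up"] < 0))
  expect_true(all(cum$percent_change[cum$direction == "down"] > 0))
  # ... and the changes are small relative to the perturbation
  expect_true(all(abs(cum$percent_change) < 20))
})

test_that("unknown tornado variables are rejected", {
  expect_error(tornado(sens_registry(), simulation_config(n_iterations = 2),
                       variables = "exchange_rate"),
               "unknown tornado variable")
})

test_that("mean spending is nonincreasing in the program correlation", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 400, seed = 4)
  sweep <- correlation_sweep(reg, cfg, rho_values = c(0, 0.5, 1))
  expect_true(all(diff(sweep$cumulative_spending_discounted) <= 0))
  expect_true(all(diff(sweep$mean_approvals) <= 0))
})

test_that("with one program per disease the correlation is immaterial", {
  reg <- toy_registry(4, programs_each = 1, area = "Oncology",
                      category = "cancer", incidence = 1200,
                      prevalence = 10000)
  cfg <- simulation_config(n_iterations = 600, seed = 5)
  sweep <- correlation_sweep(reg, cfg, rho_values = c(0, 1))
  # marginal approval probability is one program's PoS at any correlation;
  # means agree up to Monte Carlo error
  expect_equal(sweep$mean_approvals[1], sweep$mean_approvals[2],
               tolerance = 0.12)
  expect_equal(sweep$cumulative_spending_discounted[1],
               sweep$cumulative_spending_discounted[2], tolerance = 0.15)
})

test_that("comonotone equal-PoS programs approve all diseases or none", {
  reg <- toy_registry(5, programs_each = 1, area = "CNS")
  reg <- gtbudget:::prepare_registry(reg)
  programs <- unique(reg$trials[, c("program_id", "disease_id")])
  programs$therapeutic_area <- "CNS"
  set.seed(6)
  counts <- replicate(500, sum(simulate_successes(programs,
                                                  correlation = 1)))
  expect_true(all(counts %in% c(0L, 5L)))
})

test_that("uptake sweep is anchored at the baseline and monotone below it", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 30, seed = 7)
  # below ~25% spending rises with the fraction; far above it the stock
  # is consumed while penetration is still ramping, so the curve flattens
  # and can turn over -- only the low range is monotone
  sweep <- uptake_sweep(reg, cfg, fractions = c(0.05, 0.15, 0.25))
  expect_equal(sweep$percent_change_vs_baseline[3], 0)
  expect_lt(sweep$percent_change_vs_baseline[1], 0)
  expect_true(all(diff(sweep$cumulative_spending_discounted) >= 0))
  expect_equal(sweep$half_life_months[3], 28.91, tolerance = 1e-3)
})

test_that("pipeline trend fit matches exact and noisy linear counts", {
  exact <- fit_pipeline_trend(rep(2015:2017, times = c(2, 4, 6)))
  expect_equal(exact$slope, 2)
  expect_equal(exact$rate(2018), 8)
  flat <- fit_pipeline_trend(rep(2015:2018, times = c(3, 3, 3, 3)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$rate(2030), 3)
  # extrapolation below zero is truncated
  falling <- fit_pipeline_trend(rep(2014:2016, times = c(5, 3, 1)))
  expect_equal(falling$rate(2020), 0)
  expect_error(fit_pipeline_trend(c(2015, 2015)), "distinct years")

  set.seed(8)
  years <- 2005:2019
  counts <- pmax(0, round(2 + 1.5 * (years - 2005) + rnorm(15, 0, 2)))
  obs <- rep(years, counts)
  fit <- fit_pipeline_trend(obs)
  se <- summary(lm(counts ~ years))$coefficients["years", "Std. Error"]
  expect_lt(abs(fit$slope - 1.5), 3 * se)
})

test_that("Poisson pipeline arrivals have the right mean; zero rate adds none", {
  reg <- gtbudget:::prepare_registry(toy_registry(3))
  flat12 <- fit_pipeline_trend(rep(2015:2018, times = c(12, 12, 12, 12)))
  set.seed(9)
  arrivals <- replicate(200, {
    aug <- simulate_pipeline_entry(flat12, reg, years = 2020:2021)
    nrow(aug$diseases) - 3
  })
  expect_equal(mean(arrivals), 24, tolerance = 3 * sqrt(24 / 200) / 24)

  none <- fit_pipeline_trend(rep(2014:2016, times = c(5, 3, 1)))
  expect_identical(simulate_pipeline_entry(none, reg), reg)
})

test_that("a zero-rate pipeline scenario reproduces the baseline exactly", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 20, seed = 10)
  none <- fit_pipeline_trend(rep(2014:2016, times = c(5, 3, 1)))
  sc <- pipeline_scenario(reg, cfg, trend = none)
  expect_equal(sc$extended$monthly, sc$baseline$monthly)
  expect_equal(sc$extended$cumulative, sc$baseline$cumulative)
})

test_that("added pipeline programs never decrease approvals or spending", {
  reg <- sens_registry()
  cfg <- simulation_config(n_iterations = 30, seed = 11)
  flat <- fit_pipeline_trend(rep(2016:2019, times = c(2, 2, 2, 2)))
  sc <- pipeline_scenario(reg, cfg, trend = flat)
  expect_gte(sc$extended$cumulative$approvals,
             sc$baseline$cumulative$approvals)
  expect_gte(sc$extended$cumulative$spending_nominal[["mean"]],
             sc$baseline$cumulative$spending_nominal[["mean"]])
  expect_gte(sc$extended$cumulative$patients,
             sc$baseline$cumulative$patients)
})
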