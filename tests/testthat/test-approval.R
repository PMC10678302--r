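test_that("triangular lag draws have the stated support and median", {
  set.seed(1)
  x <- rtriangular(1e5)
  expect_true(all(x >= 0 & x <= 365))
  expect_equal(median(x), 182.5, tolerance = 3 * 365 / 4 / sqrt(1e5) / 182.5)
  expect_equal(mean(x), 182.5, tolerance = 3 * 365 / 4 / sqrt(1e5) / 182.5)
  expect_equal(rtriangular(3, 100, 100, 100), rep(100, 3))
})

test_that("gamma duration fit recovers simulated parameters within 5%", {
  set.seed(2)
  n <- 1e4
  dur <- rgamma(n, shape = 2, scale = 300)
  trials <- make_trial(sprintf("T%05d", 1:n), "D1",
                       start = "2018-01-01", end = NA)
  trials$end_date <- trials$start_date + dur
  fit <- fit_duration_gamma(trials)
  expect_equal(fit$shape, 2, tolerance = 0.05)
  expect_equal(1 / fit$rate, 300, tolerance = 0.05)
})

test_that("degenerate or insufficient durations are rejected", {
  same <- make_trial(c("T1", "T2", "T3"), "D1",
                     start = "2018-01-01", end = "2019-01-01")
  expect_error(fit_duration_gamma(same), "degenerate")
  one <- make_trial("T1", "D1", start = "2018-01-01", end = "2019-01-01")
  expect_error(fit_duration_gamma(one), "at least 2")
})

test_that("end-date imputation is seeded, additive and leaves complete data alone", {
  reg <- toy_registry(3)
  g <- list(shape = 4, rate = 4 / 600)
  expect_identical(impute_end_dates(reg, g), reg)

  reg$trials$end_date[2:3] <- NA
  set.seed(3); a <- impute_end_dates(reg, g)
  set.seed(3); b <- impute_end_dates(reg, g)
  expect_identical(a, b)
  expect_false(anyNA(a$trials$end_date))
  expect_true(all(a$trials$end_date >= a$trials$start_date))

  # near-degenerate duration distribution: end ~= start + mean
  tight <- list(shape = 1e8, rate = 1e8 / 600)
  set.seed(4); c <- impute_end_dates(reg, tight)
  expect_true(all(abs(as.numeric(c$trials$end_date[2:3] -
                                   c$trials$start_date[2:3]) - 600) <= 1))
})

test_that("copula success draws preserve marginals and dependence structure", {
  programs <- data.frame(
    program_id = c("P1", "P2", "P3"),
    therapeutic_area = rep("CNS", 3),  # PoS 0.370
    stringsAsFactors = FALSE)
  q <- default_pos_table()[["CNS"]]
  n <- 2e4

  # independent draws: disease-level frequency matches 1-(1-q)^3
  set.seed(5)
  any_succ <- replicate(n, any(simulate_successes(programs,
                                                  correlation = 0)))
  p_expect <- 1 - (1 - q)^3
  expect_equal(mean(any_succ), p_expect,
               tolerance = 3 * sqrt(p_expect * (1 - p_expect) / n) / p_expect)

  # comonotone draws: flags identical within each draw, frequency q
  set.seed(6)
  flags <- replicate(n, simulate_successes(programs, correlation = 1))
  expect_true(all(apply(flags, 2, function(f) all(f) || !any(f))))
  expect_equal(mean(flags[1, ]), q,
               tolerance = 3 * sqrt(q * (1 - q) / n) / q)

  expect_error(simulate_successes(programs, correlation = 1.2),
               "correlation")
})

test_that("approval rules: prior approvals, stale trials, lag arithmetic", {
  d <- rbind(
    make_disease("PRIOR", prior_approval = TRUE),
    make_disease("STALE"),
    make_disease("LIVE"))
  t <- rbind(
    make_trial("T1", "PRIOR", end = "2021-06-30"),
    make_trial("T2", "STALE", start = "2014-01-01", end = "2016-06-30"),
    make_trial("T3", "LIVE", start = "2019-01-01", end = "2022-01-01"))
  reg <- new_registry(d, t)
  flags <- setNames(rep(TRUE, 3), unique(t$program_id))

  fixed <- timing_model(c(182.5, 182.5, 182.5), c(182.5, 182.5, 182.5))
  set.seed(7)
  out <- disease_approval(reg, flags, timing = fixed)
  expect_true(out$approved[out$disease_id == "PRIOR"])
  expect_identical(out$approval_month[out$disease_id == "PRIOR"],
                   month_index(as.Date("2020-12-31")))
  expect_false(out$approved[out$disease_id == "STALE"])
  # 2022-01-01 + 182.5 + 182.5 days = 2023-01-01 -> month 36
  expect_identical(out$approval_month[out$disease_id == "LIVE"],
                   month_index(as.Date("2023-01-01")))

  # no successes: only the prior approval survives
  none <- setNames(rep(FALSE, 3), unique(t$program_id))
  set.seed(8)
  out2 <- disease_approval(reg, none, timing = fixed)
  expect_identical(out2$approved, c(TRUE, FALSE, FALSE))
})

test_that("approval months never precede the trial end or the simulation start", {
  reg <- generate_registry(20, 40, seed = 33)
  reg <- complete_epidemiology(adjust_overlaps(reg))
  g <- fit_duration_gamma(reg$trials)
  for (s in 1:20) {
    set.seed(s)
    regi <- impute_end_dates(reg, g)
    programs <- unique(regi$trials[, c("program_id", "disease_id")])
    programs$therapeutic_area <- regi$diseases$therapeutic_area[
      match(programs$disease_id, regi$diseases$disease_id)]
    flags <- simulate_successes(programs, correlation = 0.9)
    out <- disease_approval(regi, flags)
    ok <- out$approved & !regi$diseases$prior_approval
    if (!any(ok)) next
    last_end <- vapply(out$disease_id[ok], function(id) {
      max(month_index(regi$trials$end_date[regi$trials$disease_id == id]))
    }, integer(1))
    expect_true(all(out$approval_month[ok] >= pmax(last_end, 0L)))
    expect_true(all(out$approval_month[ok] >= 0L))
  }
})

test_that("expected approvals under independence match the analytic value", {
  # 6 one-program diseases + 2 three-program diseases, no prior approvals
  reg6 <- toy_registry(6, programs_each = 1, area = "Oncology",
                       category = "cancer")
  reg2 <- toy_registry(2, programs_each = 3, area = "CNS")
  reg2$diseases$disease_id <- paste0("X", reg2$diseases$disease_id)
  reg2$trials$disease_id <- paste0("X", reg2$trials$disease_id)
  reg2$trials$program_id <- paste0("X", reg2$trials$program_id)
  reg2$trials$trial_id <- paste0("X", reg2$trials$trial_id)
  reg <- new_registry(rbind(reg6$diseases, reg2$diseases),
                      rbind(reg6$trials, reg2$trials))
  pos <- default_pos_table()
  expected <- 6 * pos[["Oncology"]] + 2 * (1 - (1 - pos[["CNS"]])^3)

  n <- 5e3
  programs <- unique(reg$trials[, c("program_id", "disease_id")])
  programs$therapeutic_area <- reg$diseases$therapeutic_area[
    match(programs$disease_id, reg$diseases$disease_id)]
  set.seed(9)
  approvals <- replicate(n, {
    flags <- simulate_successes(programs, correlation = 0)
    agg <- tapply(flags[programs$program_id], programs$disease_id, any)
    sum(agg)
  })
  sd_theory <- sqrt(6 * pos[["Oncology"]] * (1 - pos[["Oncology"]]) +
                      2 * 0.75 * 0.25)
  expect_equal(mean(approvals), unname(expected),
               tolerance = 3 * sd_theory / sqrt(n) / expected)

  # positive dependence can only lower P(at least one success)
  set.seed(10)
  approvals_hi <- replicate(n, {
    flags <- simulate_successes(programs, correlation = 1)
    sum(tapply(flags[programs$program_id], programs$disease_id, any))
  })
  expect_lte(mean(approvals_hi), mean(approvals))
  expect_gte(mean(approvals_hi) + 3 * sd_theory / sqrt(n),
             6 * pos[["Oncology"]] + 2 * pos[["CNS"]])
})
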