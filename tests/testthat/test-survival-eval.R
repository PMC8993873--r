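test_that("Kaplan-Meier cumulative risk matches the hand-computed example", {
  # three subjects, events at t=1 and t=2, censoring at t=2.5:
  # S(2) = (1 - 1/3) * (1 - 1/2) = 1/3, cumulative risk 2/3
  km <- km_cumulative_risk(c(1, 2.5, 2), c(1, 0, 1), t = 2)
  expect_equal(km$risk, 2 / 3, tolerance = 1e-12)
  expect_equal(km$n_events, 2)
  expect_equal(km_cumulative_risk(c(3, 4, 5), c(0, 0, 0), 2)$risk, 0)
  expect_equal(km_cumulative_risk(c(0.5, 1, 1.5), c(1, 1, 1), 2)$risk, 1)
  expect_error(km_cumulative_risk(numeric(0), numeric(0), 2), "empty")
})

test_that("incidence rates follow the Wald formula", {
  r <- incidence_rate(rep(10, 100), rep(c(1, 0), c(10, 90)))
  expect_equal(r$rate, 10)
  r2 <- incidence_rate(rep(1, 10000), rep(c(1, 0), c(100, 9900)))
  expect_equal(r2$rate, 10)
  expect_equal(r2$upper - r2$rate, qnorm(0.975) * 1000 * sqrt(100) / 10000,
               tolerance = 1e-12)
  expect_warning(r0 <- incidence_rate(rep(1, 10), rep(0, 10)), "zero events")
  expect_equal(c(r0$rate, r0$lower, r0$upper), c(0, 0, 0))
  expect_error(incidence_rate(numeric(0), numeric(0)), "person-time")
})

test_that("the hazard ratio per SD is scale invariant and recovers truth", {
  d <- gen_calibrated(5000, seed = 61, beta = 0)   # lp independent of outcome
  h1 <- cox_hr_per_sd(d$time, d$event, d$lp)
  expect_gt(1, h1$lower); expect_lt(1, h1$upper)
  d2 <- gen_calibrated(20000, seed = 62, beta = log(2.5))
  h2 <- cox_hr_per_sd(d2$time, d2$event, d2$lp)
  expect_gt(2.5, h2$lower); expect_lt(2.5, h2$upper)
  h3 <- cox_hr_per_sd(d2$time, d2$event, 2 * d2$lp)
  expect_equal(h2$hr, h3$hr, tolerance = 1e-9)
  expect_error(cox_hr_per_sd(d$time, d$event, rep(1, nrow(d))), "variance")
})

test_that("the IPCW concordance equals brute-force pairwise concordance", {
  set.seed(63)
  n <- 200
  lp <- rnorm(n)
  time <- rexp(n, 0.1 * exp(lp))          # uncensored
  event <- rep(1L, n)
  p <- 1 - exp(-0.5 * exp(lp))
  c_pkg <- ipcw_cindex(time, event, p)$c_index
  c_bf <- brute_cindex(time, event, p)
  expect_equal(c_pkg, c_bf, tolerance = 1e-12)
  # with ties in the predictions
  p_tied <- round(p, 1)
  expect_equal(ipcw_cindex(time, event, p_tied)$c_index,
               brute_cindex(time, event, p_tied), tolerance = 1e-12)
})

test_that("concordance hits its closed-form anchors", {
  # perfect ordering, no censoring
  set.seed(72)
  time <- sort(runif(50, 1, 10))
  p <- rev(sort(runif(50)))               # highest risk fails first
  expect_equal(ipcw_cindex(time, rep(1, 50), p)$c_index, 1)
  # random predictions: c ~ 0.5
  d <- gen_calibrated(5000, seed = 64)
  set.seed(65)
  c_rand <- ipcw_cindex(d$time, d$event, runif(5000), horizon = 5)$c_index
  expect_lt(abs(c_rand - 0.5), 0.02)
  expect_error(ipcw_cindex(c(1, 2), c(0, 0), c(0.1, 0.2)), "comparable")
})

# construct data where each risk group's KM-observed risk equals its mean
# predicted risk exactly (no censoring before the horizon)
gnd_exact_data <- function(p_groups, n_per = 100, horizon = 5) {
  time <- c(); event <- c(); p <- c()
  for (pg in p_groups) {
    k <- round(pg * n_per)
    time <- c(time, seq(0.5, horizon - 0.5, length.out = k),
              rep(horizon + 1, n_per - k))
    event <- c(event, rep(1L, k), rep(0L, n_per - k))
    p <- c(p, rep(pg, n_per))
  }
  data.frame(time = time, event = event, p = p)
}

test_that("the GND statistic is zero when observed equals predicted", {
  d <- gnd_exact_data(seq(0.05, 0.50, 0.05))
  g <- gnd_test(d$time, d$event, d$p, horizon = 5, n_groups = 10)
  expect_equal(g$chi2, 0, tolerance = 1e-12)
  expect_equal(g$p_value, 1)
  expect_equal(g$n_groups, 10)
  expect_equal(g$df, 9)
})

test_that("GND groups with <5 events merge into a neighbor", {
  d <- gnd_exact_data(c(0.03, seq(0.10, 0.50, 0.05)))   # first group: 3 events
  g <- gnd_test(d$time, d$event, d$p, horizon = 5, n_groups = 10)
  expect_equal(g$n_groups, 9)
  expect_equal(g$df, 8)
  expect_error(gnd_test(d$time, d$event, d$p, 5, n_groups = 1), "n_groups")
})

test_that("the ICI falls back to the overall KM risk for constant predictions", {
  set.seed(66)
  n <- 20000
  time <- rexp(n, -log(1 - 0.15) / 5)     # true 5-year incidence 0.15
  event <- as.integer(time <= 5)
  time <- pmin(time, 5)
  expect_warning(r <- ici(time, event, rep(0.10, n), horizon = 5), "fall|KM")
  expect_true(r$fallback)
  expect_lt(abs(r$ici - 0.05), 0.01)
})

test_that("bootstrap confidence intervals are deterministic under a seed", {
  d <- gen_calibrated(1500, seed = 67)
  r1 <- ici(d$time, d$event, d$p, horizon = 5, n_boot = 40, seed = 7)
  r2 <- ici(d$time, d$event, d$p, horizon = 5, n_boot = 40, seed = 7)
  expect_identical(c(r1$lower, r1$upper), c(r2$lower, r2$upper))
  expect_true(r1$lower <= r1$ici && r1$ici <= r1$upper)
})

test_that("the calibration slope detects LP inflation and ignores re-centering", {
  d <- gen_calibrated(20000, seed = 68)
  s1 <- calibration_slope(d$time, d$event, d$p)
  expect_gt(1, s1$lower); expect_lt(1, s1$upper)
  # doubling the LP before risk conversion halves the slope
  p_infl <- 1 - exp(-0.02 * 5 * exp(2 * d$lp))
  s2 <- calibration_slope(d$time, d$event, p_infl)
  expect_lt(abs(s2$slope - 0.5), 0.07)
  # recalibration-in-the-large shifts cloglog(p) additively: slope unchanged
  p_shift <- 1 - exp(-0.05 * 5 * exp(d$lp - 0.3))
  s3 <- calibration_slope(d$time, d$event, p_shift)
  expect_equal(s1$slope, s3$slope, tolerance = 1e-8)
  expect_error(calibration_slope(d$time, d$event, rep(0.1, nrow(d))),
               "degenerate")
})

test_that("sample comparison is null on identical samples and reproducible", {
  d <- gen_calibrated(1200, seed = 69)
  a <- data.frame(time = d$time, event = d$event, p = d$p)
  cmp <- compare_samples(a, a, horizon = 5, n_boot = 60, seed = 3)
  expect_equal(cmp$ici_diff, 0)
  expect_equal(cmp$slope_diff, 0)
  expect_gt(cmp$ici_p, 0.5)
  cmp2 <- compare_samples(a, a, horizon = 5, n_boot = 60, seed = 3)
  expect_identical(cmp$ici_p, cmp2$ici_p)
  expect_warning(compare_samples(a, a, 5, n_boot = 5, seed = 1,
                                 ids_a = "x", ids_b = "x"), "independence")
})

test_that("risk-stratified KM orders strata and keeps at-risk counts monotone", {
  d <- gen_calibrated(5000, seed = 70)
  out <- risk_stratified_km(d$time, d$event, d$p, c(0.025, 0.05), horizon = 5)
  tab <- out$table
  expect_equal(nrow(tab), 3)
  expect_true(all(diff(tab$risk_at_horizon) > 0))   # calibrated generator
  for (s in unique(out$curves$stratum)) {
    cu <- out$curves[out$curves$stratum == s, ]
    expect_true(all(diff(cu$n_risk) <= 0))
  }
  expect_warning(
    one <- risk_stratified_km(d$time, d$event, rep(0.01, nrow(d)), 0.5, 5),
    "omitted")
  expect_equal(nrow(one$table), 1)
})
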