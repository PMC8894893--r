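mk_scan <- function(values, mz = 15, extra_mz = 28, extra_val = 10) {
  n <- length(values)
  rbind(
    data.frame(elapsed_s = seq(0, by = 18, length.out = n), mz = mz,
               signal = values),
    data.frame(elapsed_s = seq(0, by = 18, length.out = n), mz = extra_mz,
               signal = extra_val)
  )
}

test_that("stable_average takes the per-channel mean of the final readouts", {
  sc <- mk_scan(c(9, 9, 1, 2, 3, 4, 5))
  avg <- stable_average(sc, n_last = 5)
  expect_equal(avg[["15"]], 3)
  expect_equal(avg[["28"]], 10)
  expect_equal(stable_average(sc, n_last = 1)[["15"]], 5)
  expect_equal(stable_average(mk_scan(rep(7, 6)))[["15"]], 7)
  expect_error(stable_average(mk_scan(1:3), n_last = 5, id = "b1 d0"),
               "b1 d0")
  bad <- mk_scan(1:6)
  bad$elapsed_s[1:2] <- c(18, 0)
  expect_error(stable_average(bad), "not time-ordered")
})

test_that("calibrated_ratio applies the linear curve and clamps at zero", {
  ident <- calibration_curve("CH4", 1, 0)
  expect_equal(calibrated_ratio(3, 6, ident), 0.5)
  expect_equal(calibrated_ratio(1, 4, calibration_curve("CH4", 2, 0)), 0.5)
  expect_warning(
    r <- calibrated_ratio(0.05, 1, calibration_curve("CO2", 1, -0.1)),
    "clamped")
  expect_equal(r, 0)
  expect_error(calibrated_ratio(1, 0, ident), "N2 signal")
})

test_that("headspace_fractions matches direct substitution and sums to one", {
  expect_equal(headspace_fractions(0, 0),
               c(F_CH4 = 0, F_CO2 = 0, F_N2 = 1))
  expect_equal(headspace_fractions(1, 1),
               c(F_CH4 = 1, F_CO2 = 1, F_N2 = 1) / 3)
  expect_equal(headspace_fractions(2, 1),
               c(F_CH4 = 0.5, F_CO2 = 0.25, F_N2 = 0.25))
  expect_error(headspace_fractions(-0.1, 0), "non-negative")
  # property: sums to 1 and matches substitution over random ratios
  set.seed(7)
  r1 <- stats::rexp(5000); r2 <- stats::rexp(5000)
  f <- headspace_fractions(r1, r2)
  expect_lt(max(abs(rowSums(f) - 1)), 1e-12)
  expect_equal(f[, "F_CH4"], r1 / (r1 + r2 + 1))
})

test_that("monotone calibration preserves ordering of fractions", {
  curve <- calibration_curve("CH4", slope = 1.7, intercept = 0.01)
  set.seed(11)
  sig <- sort(stats::runif(20, 0, 5))
  r <- calibrated_ratio(sig, 10, curve)
  f <- headspace_fractions(r, rep(0.2, 20))
  expect_true(all(diff(f[, "F_CH4"]) > 0))
})

test_that("headspace_volume accumulates strictly prior withdrawals", {
  ev <- data.frame(day = c(0, 2, 4), liquid_mL = 6)
  expect_equal(headspace_volume(ev, 0), 300)              # T0
  expect_equal(headspace_volume(ev, 5), 318)              # 3 prior events
  expect_equal(headspace_volume(NULL, 10), 300)
  expect_equal(headspace_volume(ev, 4), 312)              # current excluded
  expect_equal(headspace_volume(ev, 4, include_current = TRUE), 318)
  expect_error(headspace_volume(data.frame(day = c(2, 0), liquid_mL = 6), 3),
               "time-ordered")
})

test_that("moles_in_headspace follows PV/RT", {
  expect_equal(moles_in_headspace(0, 300), 0)
  n1 <- moles_in_headspace(0.1, 300)
  expect_equal(n1, 0.1 * 0.3 / (0.082057 * 298))
  expect_equal(n1, 1.227e-3, tolerance = 1e-3)
  expect_equal(moles_in_headspace(1, 300), 10 * n1)
  expect_error(moles_in_headspace(1.2, 300), "within")
  expect_error(moles_in_headspace(0.5, -1), "positive")
})

test_that("rga_gas_consumed converts sampling time to volume", {
  expect_equal(rga_gas_consumed(0), 0)
  expect_equal(rga_gas_consumed(26), 1)
  expect_equal(rga_gas_consumed(180), 180 / 26)
  expect_equal(rga_gas_consumed(180, nominal = TRUE), 7)
})

test_that("cumulative_methane applies the prior-removal correction", {
  # single timepoint: production equals what is present
  s1 <- data.frame(day = 0, F_CH4 = 0.05, V_mL = 300, gas_removed_mL = 7)
  r1 <- cumulative_methane(s1)
  expect_equal(r1$n_produced, r1$n_present)
  # explicit arithmetic: second point adds back first removal only
  s2 <- data.frame(day = c(0, 2), F_CH4 = c(0.05, 0.10),
                   V_mL = c(300, 306), gas_removed_mL = c(7, 7))
  r2 <- cumulative_methane(s2)
  expect_equal(r2$n_produced[2],
               moles_in_headspace(0.10, 306) + 0.05 * 0.007 / (0.082057 * 298))
  # zero methane at first point: no correction at second
  s3 <- transform(s2, F_CH4 = c(0, 0.10))
  r3 <- cumulative_methane(s3)
  expect_equal(r3$n_produced[2], r3$n_present[2])
  # include_current credits the current draw too
  r2b <- cumulative_methane(s2, include_current = TRUE)
  expect_equal(r2b$n_produced[2],
               r2$n_produced[2] + moles_in_headspace(0.10, 7))
  expect_error(cumulative_methane(s2[2:1, ]), "time-ordered")
})

test_that("correction is monotone and removals accumulate", {
  set.seed(3)
  inc <- stats::runif(10, 0, 2e-4)
  ob <- oracle_bottle(inc, days = seq(0, 27, by = 3))
  r <- cumulative_methane(ob[c("day", "F_CH4", "V_mL", "gas_removed_mL")])
  expect_true(all(diff(r$n_removed_cum) >= 0))
  # dropping the correction strictly lowers production wherever any prior
  # F_CH4 was positive
  expect_true(all(r$n_produced[-1] > r$n_present[-1]))
})

test_that("cumulative_methane agrees with the mole-inventory oracle", {
  set.seed(123)
  for (i in 1:20) {
    days <- sort(stats::runif(12, 0, 30))
    inc <- stats::runif(12, 0, 3e-4)
    ob <- oracle_bottle(inc, days,
                        liquid_mL = stats::runif(12, 0, 8),
                        gas_mL = stats::runif(12, 0, 9))
    r <- cumulative_methane(ob[c("day", "F_CH4", "V_mL", "gas_removed_mL")])
    expect_equal(r$n_produced, ob$true_cum, tolerance = 1e-9)
  }
})

test_that("production_rate and max_rate_window", {
  # linear cumulative curve: constant rate on any window
  lin <- data.frame(day = 0:10, F_CH4 = 0, V_mL = 300, gas_removed_mL = 0,
                    n_present = 0, n_removed_cum = 0,
                    n_produced = 1e-4 * (0:10))
  expect_equal(production_rate(lin, c(2, 7)), 1e-4)
  expect_equal(production_rate(lin, c(1.5, 3.25)), 1e-4)  # interpolated
  expect_error(production_rate(lin, c(-1, 5)), "outside")
  expect_error(production_rate(lin, c(5, 5)), "day_a < day_b")
  # flat series: zero rate, first window wins the tie
  flat <- transform(lin, n_produced = 1e-3)
  expect_equal(production_rate(flat, c(0, 10)), 0)
  mw <- max_rate_window(flat, 3)
  expect_equal(mw$window, c(0, 3))
  expect_equal(mw$rate, 0)
  # logistic: the window containing the inflection wins; oracle = exhaustive
  days <- 0:30
  logi <- data.frame(day = days, F_CH4 = 0, V_mL = 300, gas_removed_mL = 0,
                     n_present = 0, n_removed_cum = 0,
                     n_produced = 2e-3 / (1 + exp(-0.5 * (days - 15))))
  mw <- max_rate_window(logi, 3)
  all_rates <- vapply(0:27, function(a) production_rate(logi, c(a, a + 3)), 0)
  expect_equal(mw$rate, max(all_rates))
  expect_true(mw$window[1] <= 15 && 15 <= mw$window[2])
  # monotone-convex series: last window
  conv <- transform(lin, n_produced = (0:10)^2 * 1e-5)
  expect_equal(max_rate_window(conv, 2)$window, c(8, 10))
  expect_error(max_rate_window(lin[1:2, ], 50), "shorter")
})
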