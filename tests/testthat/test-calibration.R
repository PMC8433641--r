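test_that("homoscedasticity test reproduces the extreme-level variance ratio", {
  g <- extreme_level_responses()
  h <- homoscedasticity_test(g$low, g$high, alpha = 0.01)
  expect_equal(round(h$sd_low, 3), 11.533)
  expect_equal(round(h$sd_high, 0), 5398)
  expect_equal(h$f_cal, 219113.642, tolerance = 1e-4)
  expect_equal(h$f_crit, 99.000)
  expect_false(h$homoscedastic)
})

test_that("homoscedasticity statistic follows variance scaling laws", {
  set.seed(3)
  low <- rnorm(4, 100, 5); high <- rnorm(4, 1000, 20)
  h <- homoscedasticity_test(low, high)
  expect_equal(homoscedasticity_test(low, low)$f_cal, 1)
  expect_true(homoscedasticity_test(low, low, alpha = 0.01)$homoscedastic)
  expect_equal(homoscedasticity_test(low, low * 10)$f_cal, 100)
  # common scaling leaves F unchanged; scaling one group by c scales F by c^2
  expect_equal(homoscedasticity_test(3 * low, 3 * high)$f_cal, h$f_cal)
  expect_equal(homoscedasticity_test(low, 2 * high)$f_cal, 4 * h$f_cal)
  d <- homoscedasticity_test(c(5, 5, 5), high)
  expect_true(d$degenerate)
  expect_true(is.na(d$f_cal))
})

test_that("f_critical returns upper F quantiles", {
  expect_equal(f_critical(0.99, 2, 2), 99.000)
  expect_equal(f_critical(0.50, 1, 1), 1.0)
  expect_equal(f_critical(0.95, 2, 2), 19.00)
  expect_error(f_critical(1.2, 2, 2), "in \\(0, 1\\)")
  expect_error(f_critical(0.95, 0, 2), ">= 1")
})

test_that("fit_line matches the weighted normal-equation oracle for every scheme", {
  d <- exact_line_data(slope = 2, intercept = 0)
  for (s in c("unit", "1/x", "1/x^2")) {
    f <- fit_line(d, s)
    expect_equal(f$slope, 2, tolerance = 1e-12)
    expect_equal(f$intercept, 0, tolerance = 1e-12)
    expect_equal(f$r2, 1, tolerance = 1e-12)
  }
  # heteroscedastic fixture against the closed-form 2x2 solution
  cal <- gen_calibration(calibration_sim_spec(seed = 11))
  for (s in c("unit", "1/x", "1/x^2")) {
    w <- switch(s, unit = rep(1, nrow(cal)), "1/x" = 1 / cal$conc,
                "1/x^2" = 1 / cal$conc^2)
    o <- wls_oracle(cal$conc, cal$response, w)
    f <- fit_line(cal, s)
    expect_equal(f$slope, o$slope, tolerance = 1e-10)
    expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
    # coefficients invariant under rescaling all weights
    o2 <- wls_oracle(cal$conc, cal$response, 7 * w)
    expect_equal(f$slope, o2$slope, tolerance = 1e-10)
  }
  # unit-weight fit is ordinary least squares
  ols <- wls_oracle(cal$conc, cal$response, rep(1, nrow(cal)))
  f <- fit_line(cal, "unit")
  expect_equal(f$slope, ols$slope, tolerance = 1e-10)
  expect_equal(f$intercept, ols$intercept, tolerance = 1e-10)
  expect_error(fit_line(calibration_data(c(1, 2), c(2, 4))), "3 calibration")
})

test_that("back-calculation inverts the line and round-trips", {
  cal <- gen_calibration(calibration_sim_spec(seed = 5))
  f <- fit_line(cal, "1/x^2")
  conc <- c(0.1, 1, 8, 25)
  pred <- f$intercept + f$slope * conc
  expect_equal(back_calculate(f, pred), conc, tolerance = 1e-12)
  # inverting replication-1 coefficients at the low-level response
  f2 <- f; f2$slope <- 7003.813; f2$intercept <- -61.143
  expect_equal(round(back_calculate(f2, 643), 4), 0.1005)
  expect_equal(back_calculate(f2, 10 * 2), (20 + 61.143) / 7003.813)
})

test_that("back_calc_table aggregates per level with %RE and %CV bands", {
  d <- exact_line_data(slope = 7000, intercept = -60,
                       levels = c(0.1, 1, 3, 8, 15, 25))
  f <- fit_line(d, "unit")
  tab <- back_calc_table(f, d)
  expect_equal(tab$percent_re, rep(0, 6), tolerance = 1e-9)
  expect_equal(tab$cv_percent, rep(0, 6), tolerance = 1e-9)
  expect_equal(tab$re_band, c(20, rep(15, 5)))
  expect_true(all(tab$within_band))
  # printed-mean fixture: mean 0.949 at nominal 1.000 -> %RE -5.100
  expect_equal(percent_re(0.949, 1.000), -5.100)
  # brute-force per-point recomputation on a noisy fixture
  cal <- gen_calibration(calibration_sim_spec(seed = 8))
  fw <- fit_line(cal, "1/x^2")
  tabw <- back_calc_table(fw, cal)
  for (i in seq_len(nrow(tabw))) {
    lv <- tabw$nominal[i]
    bc <- (cal$response[cal$conc == lv] - fw$intercept) / fw$slope
    expect_equal(tabw$mean_back_calc[i], mean(bc), tolerance = 1e-12)
    expect_equal(tabw$percent_re[i], 100 * (mean(bc) - lv) / lv,
                 tolerance = 1e-12)
    expect_equal(tabw$cv_percent[i], 100 * sd(bc) / mean(bc),
                 tolerance = 1e-12)
  }
})

test_that("weighting selection prefers 1/x^2 under proportional noise and unit on ties", {
  sel <- select_weighting(gen_calibration(calibration_sim_spec(seed = 21)))
  expect_equal(sel$chosen, "1/x^2")
  expect_equal(nrow(sel$table), 9)  # 3 replications x 3 schemes
  # exhaustive per-scheme oracle for the totals
  cal <- gen_calibration(calibration_sim_spec(seed = 21))
  for (s in c("unit", "1/x", "1/x^2")) {
    tot <- sum(sapply(split(seq_len(nrow(cal)), cal$replicate), function(idx) {
      w <- switch(s, unit = rep(1, length(idx)), "1/x" = 1 / cal$conc[idx],
                  "1/x^2" = 1 / cal$conc[idx]^2)
      o <- wls_oracle(cal$conc[idx], cal$response[idx], w)
      bc <- (cal$response[idx] - o$intercept) / o$slope
      sum(abs(100 * (bc - cal$conc[idx]) / cal$conc[idx]))
    }))
    expect_equal(unname(sel$totals[s]), tot, tolerance = 1e-8)
  }
  # exact line: all sums zero, tie broken toward the unit scheme
  tie <- select_weighting(exact_line_data())
  expect_equal(unname(tie$totals), rep(0, 3), tolerance = 1e-6)
  expect_equal(tie$chosen, "unit")
})

test_that("lack-of-fit ANOVA decomposes the residual sum of squares", {
  d <- exact_line_data(slope = 5, intercept = 1,
                       levels = c(1, 2, 4, 8), reps = 3)
  f <- fit_line(d, "unit")
  lof <- lack_of_fit(d, f)
  expect_equal(lof$ss_lack_of_fit, 0, tolerance = 1e-18)
  expect_true(lof$linear_ok)

  # curvature: exactly quadratic means with tiny replicate noise
  lv <- c(1, 2, 4, 8)
  conc <- rep(lv, each = 3)
  set.seed(9)
  y <- conc^2 + rnorm(length(conc), 0, 1e-3)
  dq <- calibration_data(conc, y, rep(1:3, times = 4))
  fq <- fit_line(dq, "unit")
  lofq <- lack_of_fit(dq, fq)
  expect_gt(lofq$f_lof, lofq$f_crit)
  expect_false(lofq$linear_ok)
  # manual ANOVA-table oracle
  pred <- fq$intercept + fq$slope * conc
  gm <- ave(y, conc)
  expect_equal(lofq$ss_pure_error, sum((y - gm)^2), tolerance = 1e-9)
  expect_equal(lofq$ss_lack_of_fit, sum((gm - pred)^2), tolerance = 1e-9)
  expect_equal(lofq$f_lof,
               (sum((gm - pred)^2) / 2) / (sum((y - gm)^2) / 8),
               tolerance = 1e-9)

  # sum-of-squares conservation on a seeded linear fixture
  cal <- gen_calibration(calibration_sim_spec(seed = 13))
  fw <- fit_line(cal, "1/x")
  l <- lack_of_fit(cal, fw)
  expect_equal(l$ss_lack_of_fit + l$ss_pure_error, l$ss_residual,
               tolerance = 1e-9)
  expect_error(lack_of_fit(calibration_data(c(1, 2, 3), c(2, 4, 6)), f),
               "pure error")
})

test_that("regression ANOVA matches hand-computed weighted standard errors", {
  cal <- gen_calibration(calibration_sim_spec(seed = 17))
  f <- fit_line(cal, "1/x^2")
  a <- regression_anova(cal, f)
  w <- 1 / cal$conc^2
  res <- cal$response - f$intercept - f$slope * cal$conc
  sigma2 <- sum(w * res^2) / (nrow(cal) - 2)
  xbw <- sum(w * cal$conc) / sum(w)
  sxx <- sum(w * (cal$conc - xbw)^2)
  se_b <- sqrt(sigma2 / sxx)
  se_a <- sqrt(sigma2 * (1 / sum(w) + xbw^2 / sxx))
  expect_equal(a$se_slope, se_b, tolerance = 1e-8)
  expect_equal(a$se_intercept, se_a, tolerance = 1e-8)
  expect_equal(a$p_slope, 2 * pt(-abs(f$slope / se_b), nrow(cal) - 2),
               tolerance = 1e-8)
  expect_equal(a$p_intercept, 2 * pt(-abs(f$intercept / se_a), nrow(cal) - 2),
               tolerance = 1e-8)
  expect_false(a$degenerate)
  expect_lt(a$p_slope, 0.05)

  # noiseless limit flagged degenerate with p_slope ~ 0
  d0 <- exact_line_data(slope = 3, intercept = 0)
  a0 <- regression_anova(d0, fit_line(d0, "unit"))
  expect_true(a0$degenerate)
  expect_lt(a0$p_slope, 1e-10)
})

test_that("intercept test holds its size when the true intercept is zero", {
  p <- vapply(1:100, function(s) {
    cal <- gen_calibration(calibration_sim_spec(true_intercept = 0, seed = s))
    regression_anova(cal, fit_line(cal, "1/x^2"))$p_intercept
  }, numeric(1))
  expect_gte(mean(p > 0.05), 0.90)
})
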