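test_that("plate count, tailing factor and resolution follow the USP forms", {
  expect_equal(plate_count(1.0, 0.1), 554)
  expect_equal(round(plate_count(2.427, 0.0503), 0), 12898)
  expect_equal(plate_count(2, 0.2), plate_count(1, 0.1))  # scale invariance
  expect_error(plate_count(-1, 0.1), "> 0")

  expect_equal(tailing_factor(0.2, 0.1), 1.0)
  expect_equal(tailing_factor(0.3, 0.1), 1.5)
  expect_error(tailing_factor(0.1, 0.2), "cannot exceed")

  expect_equal(resolution(1.6, 2.5, 0.06, 0.06), 15)
  expect_equal(resolution(2, 2 + 1e-9, 0.1, 0.1), 2e-9 / 0.2)
  expect_error(resolution(2.5, 1.6, 0.06, 0.06), "exceed")
  # dimensionless under common time rescaling
  expect_equal(resolution(3.2, 5, 0.12, 0.12),
               resolution(1.6, 2.5, 0.06, 0.06))
})

test_that("tailing of a synthetic tailed peak matches the numeric 5%-height oracle", {
  t <- seq(1.8, 3.2, length.out = 8001)
  y <- peak_shape(t, 2.4, sigma = 0.02, tau = 0.01, area = 100)
  m <- measure_peak_width(t, y, 0.05)
  T <- tailing_factor(m$width, m$front)
  expect_gt(T, 1)  # exponential tail skews the rear
  expect_equal(T, m$width / (2 * m$front), tolerance = 1e-12)
  # symmetric Gaussian: tailing 1, half-height width 2.355 sigma
  yg <- peak_shape(t, 2.4, sigma = 0.02, tau = 0, area = 100)
  mg5 <- measure_peak_width(t, yg, 0.05)
  expect_equal(tailing_factor(mg5$width, mg5$front), 1, tolerance = 5e-3)
  mg50 <- measure_peak_width(t, yg, 0.5)
  expect_equal(mg50$width, 2 * sqrt(2 * log(2)) * 0.02, tolerance = 1e-4)
})

test_that("suitability report reproduces repeatability and verdicts on the printed run", {
  rep5 <- suitability_report(suitability_injections(), resolution_rs = 29)
  expect_equal(round(rep5$rt_stats$cv_percent, 2), 0.14)
  expect_equal(rep5$area_stats$cv_percent, 0.2853, tolerance = 1e-3)
  expect_true(rep5$passed)
  expect_true(all(vapply(rep5$verdicts, `[[`, logical(1), "passed")))

  ident <- data.frame(injection_id = 1:5, rt_min = rep(2.4, 5),
                      area = rep(5e4, 5))
  expect_warning(r0 <- suitability_report(ident), "width")
  expect_equal(r0$rt_stats$cv_percent, 0)
  expect_equal(r0$area_stats$cv_percent, 0)

  bump <- suitability_injections()
  bump$area[1] <- bump$area[1] * 1.1
  rb <- suitability_report(bump)
  expect_equal(rb$area_stats$cv_percent,
               100 * sd(bump$area) / mean(bump$area), tolerance = 1e-12)
  expect_error(suitability_report(suitability_injections()[1:3, ]),
               "at least 5")
})

test_that("suitability metrics are invariant under injection reordering", {
  inj <- suitability_injections()
  a <- suitability_report(inj)
  b <- suitability_report(inj[sample(5), ])
  expect_equal(a$rt_stats$cv_percent, b$rt_stats$cv_percent)
  expect_equal(a$plates, b$plates)
})

test_that("percent remaining is a linear pass-through of the response ratio", {
  expect_equal(percent_remaining(100, 100), 100)
  expect_equal(percent_remaining(77.65, 100), 77.65)
  expect_equal(percent_remaining(0, 100), 0)
  expect_equal(percent_remaining(102.2, 100), 102.2)  # > 100 not clamped
  expect_equal(percent_remaining(c(1, 2, 4), 8), c(12.5, 25, 50))
  expect_error(percent_remaining(50, 0), "> 0")
  st <- stress_table(data.frame(condition = c("acid", "control"),
                                incubation_h = c(3, 0),
                                response = c(3882.5, 5000),
                                control_response = 5000))
  expect_equal(st$remaining_percent, c(77.65, 100))
})

test_that("robustness table summarises each condition and flags violations", {
  inj <- suitability_injections()
  same <- robustness_table(list(a = inj, b = inj))
  expect_equal(same$rt_cv[1], same$rt_cv[2])
  expect_true(all(same$passed))
  # %CV 0.84 passes the < 2% limit
  expect_true(check_rule(acceptance_rule("%CV", upper = 2), 0.84)$passed)

  perturbed <- inj
  perturbed$area <- perturbed$area * c(1, 1, 1, 1, 1.2)
  tab <- robustness_table(list(nominal = inj, shifted = perturbed))
  expect_equal(tab$area_cv[tab$condition == "shifted"],
               summarize_values(perturbed$area)$cv_percent)
  expect_false(tab$passed[tab$condition == "shifted"])
  expect_error(robustness_table(list(a = inj)), ">= 2 conditions")
})
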