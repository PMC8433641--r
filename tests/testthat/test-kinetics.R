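test_that("noiseless fits of matching order recover exact parameters with r^2 = 1", {
  tt <- seq(0, 24, by = 2)
  first <- kinetic_timecourse(tt, 5 * exp(-0.045 * tt))
  f1 <- fit_order(first, "first")
  expect_equal(f1$k, 0.045, tolerance = 1e-10)
  expect_equal(f1$c0_est, 5, tolerance = 1e-10)
  expect_equal(f1$r2, 1, tolerance = 1e-12)

  zero <- kinetic_timecourse(tt, 5 - 0.1 * tt)
  f0 <- fit_order(zero, "zero")
  expect_equal(f0$k, 0.1, tolerance = 1e-10)
  expect_equal(f0$r2, 1, tolerance = 1e-12)

  second <- kinetic_timecourse(tt, 5 / (1 + 0.01 * 5 * tt))
  f2 <- fit_order(second, "second")
  expect_equal(f2$k, 0.01, tolerance = 1e-10)
  expect_equal(f2$c0_est, 5, tolerance = 1e-10)
})

test_that("fit_order equals an independent least-squares oracle on noisy data", {
  tcs <- gen_decay(decay_sim_spec(seed = 31))
  tc <- tcs[[1]]
  f <- fit_order(tc, "first")
  o <- wls_oracle(tc$time_h, log(tc$conc), rep(1, nrow(tc)))
  expect_equal(f$slope, o$slope, tolerance = 1e-10)
  expect_equal(f$intercept, o$intercept, tolerance = 1e-10)
  expect_equal(f$k, -o$slope, tolerance = 1e-10)
})

test_that("non-positive concentrations are dropped by default or rejected on request", {
  tt <- c(0, 2, 4, 6, 8)
  cc <- c(5, 3, 0, 1, 0.5)
  tc <- data.frame(time_h = tt, conc = cc)
  expect_warning(f <- fit_order(tc, "first"), "non-positive")
  expect_equal(f$n, 4)
  expect_error(fit_order(tc, "first", on_nonpositive = "error"), "time 4")
  expect_silent(fit_order(tc, "zero"))
  short <- data.frame(time_h = c(0, 2, 4), conc = c(5, 0, 1))
  expect_error(suppressWarnings(fit_order(short, "first")), "fewer than 3")
})

test_that("half-life follows the order's closed form and k * t1/2 = ln 2", {
  expect_equal(half_life(log(2)), 1)
  expect_equal(half_life(0.045), 15.40327, tolerance = 1e-6)
  expect_equal(half_life(0.01, "second", c0 = 5), 20)
  expect_equal(half_life(0.1, "zero", c0 = 5), 25)
  expect_error(half_life(-1), "> 0")
  expect_error(half_life(0.1, "zero"), "c0")
  for (s in 1:10) {
    tcs <- gen_decay(decay_sim_spec(k_true = 0.03 + 0.002 * s, seed = s))
    for (tc in tcs) {
      f <- fit_order(tc, "first")
      expect_identical(half_life(f$k), log(2) / f$k)
      expect_equal(f$k * half_life(f$k), log(2), tolerance = 1e-15)
    }
  }
})

test_that("order selection picks the generating order and breaks ties low", {
  tt <- seq(0, 24, by = 2)
  first3 <- lapply(1:3, function(r) {
    kinetic_timecourse(tt, 5 * exp(-0.045 * tt), replicate = r)
  })
  s1 <- select_order(first3)
  expect_equal(s1$chosen_order, "first")
  r2 <- s1$r2_table$mean_r2
  names(r2) <- s1$r2_table$order
  expect_equal(unname(r2["first"]), 1, tolerance = 1e-12)
  expect_lt(r2["zero"], 1)
  expect_lt(r2["second"], 1)

  zero3 <- lapply(1:3, function(r) {
    kinetic_timecourse(tt, 5 - 0.1 * tt, replicate = r)
  })
  expect_equal(select_order(zero3)$chosen_order, "zero")
})

test_that("replicate aggregation averages k and half-life per replicate", {
  tt <- seq(0, 24, by = 2)
  fits <- lapply(c(0.040, 0.045, 0.050), function(k) {
    fit_order(kinetic_timecourse(tt, 5 * exp(-k * tt)), "first")
  })
  s <- summarize_kinetics(fits)
  expect_equal(s$k_mean, 0.045, tolerance = 1e-10)
  expect_equal(s$t_half_mean, mean(log(2) / c(0.040, 0.045, 0.050)),
               tolerance = 1e-10)
  expect_equal(round(s$t_half_mean, 4), 15.5316)
  # the per-replicate mean exceeds ln2 / mean(k) (Jensen direction)
  expect_gt(s$t_half_mean, log(2) / s$k_mean)
  expect_equal(round(log(2) / s$k_mean, 4), 15.4033)

  same <- summarize_kinetics(fits[c(2, 2, 2)])
  expect_equal(same$k_sd, 0, tolerance = 1e-12)
  one <- summarize_kinetics(fits[2])
  expect_true(is.na(one$k_sd))
  # elementwise hand computation on a seeded triplicate
  tcs <- gen_decay(decay_sim_spec(seed = 41))
  fs <- lapply(tcs, fit_order, order = "first")
  agg <- summarize_kinetics(fs)
  ks <- vapply(fs, `[[`, numeric(1), "k")
  expect_equal(agg$k_mean, mean(ks), tolerance = 1e-12)
  expect_equal(agg$k_sd, sd(ks), tolerance = 1e-12)
  expect_equal(agg$t_half_mean, mean(log(2) / ks), tolerance = 1e-12)
})

test_that("first order is selected from noisy triplicates at the study design", {
  hits <- vapply(1:100, function(s) {
    sel <- select_order(gen_decay(decay_sim_spec(k_true = 0.04, seed = s)))
    sel$chosen_order == "first"
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("rate-constant recovery is unbiased with replicate scatter below the reported spread", {
  ks <- vapply(1:200, function(s) {
    tcs <- gen_decay(decay_sim_spec(seed = s))
    mean(vapply(tcs, function(tc) fit_order(tc, "first")$k, numeric(1)))
  }, numeric(1))
  expect_equal(mean(ks), 0.045, tolerance = 0.02)
  rep_sd <- vapply(1:50, function(s) {
    tcs <- gen_decay(decay_sim_spec(seed = s))
    sd(vapply(tcs, function(tc) fit_order(tc, "first")$k, numeric(1)))
  }, numeric(1))
  expect_true(all(rep_sd > 0))
  expect_lt(mean(rep_sd), 0.003)  # injection noise alone stays below the field spread
})
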