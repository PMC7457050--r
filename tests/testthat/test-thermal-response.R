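test_that("cubic fits recover exact polynomial data to machine precision", {
  # linear data: higher-order coefficients vanish
  ts <- thermal_series(c(5, 10, 20, 30), 1 + 2 * c(5, 10, 20, 30))
  cf <- coef(fit_cubic(ts))
  expect_equal(unname(cf), c(1, 2, 0, 0), tolerance = 1e-9)

  truth <- c(-4, 0.95, -0.021, -5e-5)
  ser <- simulate_thermal_response(truth, seq(5, 35, 2.5))
  fit <- fit_cubic(ser)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-9)
  expect_equal(predict(fit, 17), sum(truth * 17^(0:3)), tolerance = 1e-9)

  expect_error(thermal_series(c(5, 5, 5, 10), 1:4), "distinct")
})

test_that("noisy cubic coefficients are recovered without bias", {
  truth <- c(2, 1.5, -0.05, 1e-4)
  est <- t(vapply(1:100, function(s) {
    ser <- simulate_thermal_response(truth, seq(5, 35, 2.5), noise_sd = 0.5,
                                     seed = s)
    unname(coef(fit_cubic(ser)))
  }, numeric(4)))
  bias <- colMeans(est) - truth
  mc_se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 4 * mc_se + 1e-12))
})

test_that("optimum sits where the first derivative vanishes", {
  # integrate derivative (T-22)(T-50) = T^2 - 72T + 1100:
  # cubic T^3/3 - 36T^2 + 1100T has a local max at 22 (second derivative < 0)
  cf <- c(0, 1100, -36, 1 / 3)
  ser <- thermal_series(c(5, 15, 25, 40), eval_at <- sapply(c(5, 15, 25, 40),
    function(t) sum(cf * t^(0:3))))
  fit <- fit_cubic(ser)
  opt <- optimum_temperature(fit)
  expect_equal(opt$t_opt, 22, tolerance = 1e-6)
  expect_false(opt$boundary)

  # monotone increasing cubic: boundary optimum at the upper end, flagged
  mono <- fit_cubic(thermal_series(c(5, 15, 25, 40), c(1, 2, 4, 9)))
  expect_true(optimum_temperature(mono)$boundary)
  expect_equal(optimum_temperature(mono)$t_opt, 40)
})

test_that("synthetic optimum at 24 degC is recovered within 0.5 degC", {
  # ETRmax-shaped cubic: interior maximum exactly at 24 (derivative
  # 3c3(T-24)(T+40)), response at 5 degC ~15% of the peak as in chilled moss
  c3 <- -0.002
  d <- c(-960, 16, 1) # (T-24)(T+40) = T^2 + 16T - 960
  cf <- c(-17.5, 3 * c3 * d[1], 3 * c3 * d[2] / 2, c3)
  fit0 <- fit_cubic(simulate_thermal_response(cf, seq(5, 40, 2.5)))
  expect_equal(fit0$t_opt, 24, tolerance = 1e-9)

  peak <- predict(fit0, 24)
  err <- vapply(1:100, function(s) {
    ser <- simulate_thermal_response(cf, seq(5, 40, 2.5),
                                     noise_sd = 0.05 * peak, seed = s)
    fit_cubic(ser)$t_opt - 24
  }, numeric(1))
  expect_lte(median(abs(err)), 0.5)
})

test_that("q10 matches its closed form and is scale invariant", {
  expect_equal(q10(1, 2, 10, 20), 2)
  expect_equal(q10(3, 3, 5, 25), 1)
  expect_equal(q10(0.025, 0.045, 15, 25), 1.8)
  expect_error(q10(0, 1, 5, 15), "> 0")
  expect_error(q10(1, 1, 5, 5), "differ")

  set.seed(5)
  for (i in 1:50) {
    g1 <- runif(1, 0.01, 1); g2 <- runif(1, 0.01, 1)
    t1 <- runif(1, 0, 20); t2 <- t1 + runif(1, 1, 20)
    k <- runif(1, 0.1, 10)
    expect_equal(q10(k * g1, k * g2, t1, t2), q10(g1, g2, t1, t2),
                 tolerance = 1e-12)
    # swapping both rates and temperatures leaves Q10 unchanged
    expect_equal(q10(g2, g1, t2, t1), q10(g1, g2, t1, t2), tolerance = 1e-12)
  }
})

test_that("per-replicate thermal table reports mean and se of optima", {
  truth <- c(-4, 0.95, -0.021, -5e-5)
  rows <- do.call(rbind, lapply(1:4, function(r) {
    ser <- simulate_thermal_response(truth, seq(5, 35, 5), noise_sd = 0.1,
                                     seed = r)
    data.frame(replicate_id = sprintf("r%d", r),
               temperature_c = ser$temperature, response = ser$response)
  }))
  res <- fit_thermal_table(rows, "Asat")
  expect_equal(nrow(res$per_replicate), 4)
  expect_equal(res$summary$n, 4)
  expect_equal(res$summary$mean_t_opt, mean(res$per_replicate$t_opt))
  expect_lt(abs(res$summary$mean_t_opt - 21.01), 1.5)
  pooled <- fit_thermal_table(rows, "Asat", pooled = TRUE)
  expect_equal(nrow(pooled$per_replicate), 1)
})
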