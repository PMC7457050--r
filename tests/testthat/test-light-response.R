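test_that("both models vanish at zero light with initial slope AQE", {
  expect_equal(rational_model(0, 0.3, 60), 0)
  expect_equal(waiting_in_line_model(0, 0.3, 60), 0)
  eps <- 1e-6
  expect_equal(rational_model(eps, 0.3, 60) / eps, 0.3, tolerance = 1e-6)
  expect_equal(waiting_in_line_model(eps, 0.3, 60) / eps, 0.3, tolerance = 1e-6)
  expect_error(rational_model(100, -0.1, 60), "> 0")
  expect_error(waiting_in_line_model(100, 0.3, 0), "> 0")
})

test_that("rational model saturates monotonically toward ETRmax", {
  # closed form at high light: 0.3*10000 / sqrt(1 + 50^2) = 3000/sqrt(2501)
  expect_equal(rational_model(10000, 0.3, 60), 3000 / sqrt(2501))
  q <- seq(0, 5000, 10)
  v <- rational_model(q, 0.25, 80)
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 80))
})

test_that("waiting-in-line peaks at exactly ETRmax at Q* = ETRmax*e/AQE", {
  aqe <- 0.3; emax <- 60
  qstar <- emax * exp(1) / aqe
  expect_equal(qstar, 543.6564, tolerance = 1e-6)
  expect_equal(waiting_in_line_model(qstar, aqe, emax), emax)
  expect_lt(waiting_in_line_model(2 * qstar, aqe, emax), emax)
  q <- seq(1, 4 * qstar, length.out = 2000)
  expect_true(all(waiting_in_line_model(q, aqe, emax) <= emax + 1e-12))
})

test_that("photoinhibition classification keys on a high-light decline", {
  q <- c(0, 25, 50, 100, 200, 400, 800, 1600)
  sat <- light_curve(q, rational_model(q, 0.25, 80))
  expect_false(classify_photoinhibition(sat))

  qd <- c(0, 100, 300, 544, 900, 1400, 2000, 2600)
  dec <- light_curve(qd, waiting_in_line_model(qd, 0.3, 60))
  expect_true(classify_photoinhibition(dec))

  flat <- light_curve(q, rep(10, length(q)))
  expect_false(classify_photoinhibition(flat))
})

test_that("noiseless fits recover (AQE, ETRmax) for both models", {
  q <- c(0, 25, 50, 100, 200, 400, 800, 1600)
  fit_r <- fit_light_curve(light_curve(q, rational_model(q, 0.25, 80)))
  expect_identical(fit_r$model, "rational")
  expect_true(fit_r$converged)
  expect_equal(unname(coef(fit_r)), c(0.25, 80), tolerance = 1e-6)

  qd <- c(0, 100, 300, 544, 900, 1400, 2000, 2600)
  fit_w <- fit_light_curve(light_curve(qd, waiting_in_line_model(qd, 0.3, 60)))
  expect_identical(fit_w$model, "waiting_in_line")
  expect_equal(unname(coef(fit_w)), c(0.3, 60), tolerance = 1e-6)

  expect_error(light_curve(c(0, 100, 200), c(0, 1, 2)), "at least 4")
})

test_that("the auto-selected model has the lower SSE on synthetic fixtures", {
  q <- c(0, 50, 150, 400, 800, 1300, 1900, 2600)
  cases <- list(
    simulate_light_curve("rational", 0.25, 80, q, noise_sd = 1, seed = 2),
    simulate_light_curve("waiting_in_line", 0.3, 60, q, noise_sd = 1, seed = 3)
  )
  for (cv in cases) {
    auto <- fit_light_curve(cv)
    other <- setdiff(c("rational", "waiting_in_line"), auto$model)
    alt <- fit_light_curve(cv, model = other)
    expect_lte(auto$sse, alt$sse)
    expect_identical(auto$model, synthetic_truth(cv)$model)
  }
})

test_that("noisy recovery: median ETRmax error within 5% over 100 seeds", {
  q <- c(0, 25, 50, 100, 200, 400, 800, 1200, 1600)
  err <- vapply(1:100, function(s) {
    cv <- simulate_light_curve("rational", 0.25, 80, q, noise_sd = 2, seed = s)
    abs(fit_light_curve(cv, model = "rational")$etr_max - 80) / 80
  }, numeric(1))
  expect_lte(median(err), 0.05)
})

test_that("predict/residuals/coef methods are mutually consistent", {
  q <- c(0, 25, 50, 100, 200, 400, 800, 1600)
  cv <- simulate_light_curve("rational", 0.2, 50, q, noise_sd = 1, seed = 4)
  fit <- fit_light_curve(cv)
  expect_equal(predict(fit), rational_model(q, fit$aqe, fit$etr_max))
  expect_equal(sum(residuals(fit)^2), fit$sse, tolerance = 1e-10)
  expect_named(coef(fit), c("aqe", "etr_max"))
})

test_that("fit_light_curve_table fits each replicate-temperature group", {
  b <- simulate_study(seed = 12, n_replicates = 2, t_grid = c(5, 15, 25, 35))
  tab <- fit_light_curve_table(b$light_curves)
  expect_equal(nrow(tab), 8)
  expect_true(all(tab$converged))
  expect_true(all(tab$aqe > 0 & tab$etr_max > 0))
})
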