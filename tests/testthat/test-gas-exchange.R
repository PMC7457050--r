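test_that("gamma_star follows 0.5 * O / S_C/O and is linear in O", {
  expect_equal(gamma_star(210000, 2625), 40)
  expect_equal(gamma_star(2 * 210000, 2625), 80)
  expect_error(gamma_star(-1, 2625), "> 0")
  expect_error(gamma_star(210000, 0), "> 0")
})

test_that("the hand-checked variable-J worked example is exact", {
  est <- mesophyll_conductance(a_sat = 5, r_light = 1, ca = 300, etr = 42,
                               gamma_star = 40)
  expect_equal(est$cc, 200)          # 40 * (42 + 48) / (42 - 24) = 200
  expect_equal(est$gm, 0.05)         # 5 / (300 - 200)
  expect_equal(est$lm, 1 / 3)        # da/dcc = 5/200 = 0.025
  expect_equal(est$lb, 2 / 3)
  expect_length(est$flags, 0)
  # Cc from the Harley bracket agrees with ca - a_sat/gm algebraically
  expect_equal(est$cc, est$ca - est$a_sat / est$gm, tolerance = 1e-12)
})

test_that("zero assimilation gives zero conductance, flagged", {
  est <- mesophyll_conductance(0, 0, 300, 10, 40)
  expect_equal(est$gm, 0)
  expect_true("gm_zero" %in% est$flags)
  expect_true(is.na(est$lm))
})

test_that("the singularity triggers exactly at ETR <= 4(Asat + RL)", {
  expect_error(mesophyll_conductance(5, 1, 300, 24, 40), "singularity")
  expect_error(mesophyll_conductance(5, 1, 300, 23, 40), "singularity")
  # just above the pole the estimate exists (and Cc blows up toward Ca)
  est <- mesophyll_conductance(5, 1, 400, 24 + 1e-6, 1e-4)
  expect_true(is.finite(est$gm))
})

test_that("variable-J inverts the forward generator exactly on a grid", {
  gm_grid <- seq(0.005, 0.2, length.out = 20)
  cc_grid <- seq(60, 300, length.out = 20)
  worst <- 0
  for (gm_true in gm_grid) for (cc in cc_grid) {
    obs <- simulate_gas_exchange(gm_true, cc, gamma_star = 40, r_light = 1,
                                 ca = 400)
    est <- mesophyll_conductance(obs$a_sat, obs$r_light, obs$ca, obs$etr,
                                 obs$gamma_star)
    worst <- max(worst, abs(est$gm - gm_true) / gm_true)
  }
  expect_lte(worst, 1e-9)
})

test_that("limitations sum to one and lm falls as gm rises", {
  expect_equal(unname(limitation_partition(0.05, 0.05)), c(0.5, 0.5))
  set.seed(21)
  for (i in 1:100) {
    gm <- runif(1, 1e-4, 0.5)
    s <- runif(1, 1e-4, 0.5)
    lp <- limitation_partition(gm, s)
    expect_equal(sum(lp), 1, tolerance = 1e-12)
  }
  lm_seq <- limitation_partition(seq(0.01, 0.3, length.out = 50), 0.05)[, "lm"]
  expect_true(all(diff(lm_seq) < 0))
  expect_error(limitation_partition(0, 0.05), "> 0")
})

test_that("phi_co2 is gross assimilation per photon", {
  expect_equal(phi_co2(3, 1, 400), 0.01)
  expect_equal(phi_co2(-1, 1, 400), 0)
  expect_equal(phi_co2(3, 1, 800), phi_co2(3, 1, 400) / 2)
  expect_error(phi_co2(3, 1, 0), "> 0")
})

test_that("alpha-beta calibration: proportional data gives 0.42 both ways", {
  ppfd <- c(50, 100, 200, 400, 800)
  phi_psii_v <- c(0.7, 0.65, 0.55, 0.45, 0.4)
  phi_co2_v <- 0.105 * phi_psii_v
  ab_slope <- calibrate_alpha_beta(ppfd, phi_psii_v, phi_co2_v, mode = "slope")
  expect_equal(ab_slope$alpha_beta, 0.42, tolerance = 1e-9)
  ab_hi <- calibrate_alpha_beta(ppfd, phi_psii_v, phi_co2_v,
                                mode = "highest_ppfd")
  expect_equal(ab_hi$alpha_beta, 0.42, tolerance = 1e-9)
  expect_identical(ab_hi$source, "calibrated")
  expect_identical(attr(ab_hi, "mode"), "highest_ppfd")

  # single highest-PPFD point arithmetic
  ab1 <- calibrate_alpha_beta(c(100, 400, 800), c(0.6, 0.5, 0.4),
                              c(0.05, 0.045, 0.042))
  expect_equal(ab1$alpha_beta, 0.42, tolerance = 1e-9)
})

test_that("drifting phiCO2/phiPSII ratio makes the two modes disagree", {
  ppfd <- c(50, 100, 200, 400, 800)
  phi_psii_v <- c(0.7, 0.65, 0.55, 0.45, 0.4)
  ratio <- seq(0.08, 0.12, length.out = 5) # rises with PPFD
  phi_co2_v <- ratio * phi_psii_v
  hi <- calibrate_alpha_beta(ppfd, phi_psii_v, phi_co2_v, "highest_ppfd")
  sl <- calibrate_alpha_beta(ppfd, phi_psii_v, phi_co2_v, "slope")
  expect_gt(abs(hi$alpha_beta - sl$alpha_beta), 0.01)
  expect_equal(hi$alpha_beta, 4 * 0.12, tolerance = 1e-9)
})

test_that("light respiration is the negative intercept on the Yin axis", {
  ppfd <- c(20, 40, 60, 80)
  phi <- c(0.78, 0.76, 0.74, 0.72)
  x <- phi * ppfd / 4
  expect_equal(light_respiration(0.8 * x - 1, phi, ppfd)$r_light, 1,
               tolerance = 1e-9)
  expect_equal(light_respiration(0.8 * x, phi, ppfd)$r_light, 0,
               tolerance = 1e-9)
  expect_error(light_respiration(1:2, phi[1:2], ppfd[1:2]), "aligned|>= 3")

  # unbiased recovery under noise, 100 draws
  set.seed(33)
  est <- vapply(1:100, function(s) {
    y <- 0.8 * x - 1 + rnorm(length(x), 0, 0.05)
    light_respiration(y, phi, ppfd)$r_light
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 4 * sd(est) / sqrt(100) + 1e-12)
})

test_that("gas_exchange_table flags cold singular records and keeps the rest", {
  b <- simulate_study(seed = 9)
  tab <- gas_exchange_table(b$gas_exchange, gamma_star = 40,
                            alpha_beta = 0.42, r_light = 1)
  fine <- is.finite(tab$gm)
  expect_true(any(fine))
  # recovered gm matches the generator's gm(T) where defined
  tru <- 0.005 + 0.002 * pmax(tab$temperature_c[fine] - 5, 0)
  expect_equal(tab$gm[fine], tru, tolerance = 1e-6)
  expect_true(all(tab$lm[fine] + tab$lb[fine] - 1 < 1e-9, na.rm = TRUE))
  expect_equal(attr(tab, "report")$n, nrow(tab))

  # a clearly singular record is flagged, not dropped
  bad <- b$gas_exchange[1, ]
  bad$fs <- bad$fm_prime * 0.999 # near-zero phi -> tiny ETR
  tab2 <- gas_exchange_table(bad, 40, 0.42, r_light = 1)
  expect_identical(tab2$flags, "singularity")
  expect_true(is.na(tab2$gm))
})

test_that("near-zero true gm is recovered as statistically zero under noise", {
  gm_true <- 1e-4
  est <- vapply(1:60, function(s) {
    obs <- simulate_gas_exchange(gm_true, 200, 40, 1, ca = 400,
                                 noise_sd = 0.02, seed = s)
    tryCatch(mesophyll_conductance(obs$a_sat, obs$r_light, obs$ca, obs$etr,
                                   obs$gamma_star)$gm,
             error = function(e) NA_real_)
  }, numeric(1))
  est <- est[is.finite(est)]
  expect_gt(length(est), 30)
  # zero lies inside the mean +/- 2 se interval
  expect_lt(abs(mean(est)), 2 * sd(est) / sqrt(length(est)) + 2 * gm_true)
})
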