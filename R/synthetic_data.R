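# Synthetic-data generators: every input the pipeline consumes, with known
# ground truth recorded as a sidecar, so every stage is testable offline.
# Each generator is a pure function of (parameters, seed): the caller's RNG
# state is untouched, and one user seed fans out to independent per-stream
# sub-seeds.

#' Ground truth attached to a synthetic dataset
#'
#' Every generator attaches a `truth` attribute: the full parameter set plus
#' the seed, so parameter-recovery tests read the truth from the sidecar
#' rather than re-deriving it.
#'
#' @param x a generated object.
#' @return Named list of generator parameters, or `NULL`.
#' @export
synthetic_truth <- function(x) attr(x, "truth")

#' Write a ground-truth sidecar as JSON
#'
#' @param x a generated object carrying a `truth` attribute.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path) {
  tr <- synthetic_truth(x)
  if (is.null(tr)) stopf("object carries no synthetic truth")
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulate a moss canopy-surface temperature trace
#'
#' Phenomenological diurnal model of a polar-summer moss surface: a
#' sinusoidal base cycle peaking in the early afternoon, plus
#' clear-day radiative warming spikes (a Bernoulli draw per day of a
#' Gaussian-shaped midday bump), plus Gaussian sensor/weather noise. A
#' `buffering` factor in \[0, 1\] scales down both the diurnal amplitude and
#' the spikes, mimicking the thermal damping of a water-saturated canopy
#' (`buffering = 1` leaves only the mean and noise).
#'
#' The defaults emulate a midsummer East Antarctic coastal regime: 13 days
#' at 30-minute resolution with roughly 57% of records below 4 degrees C
#' and 2-3% above 14 degrees C.
#'
#' @param days number of days (>= 1); default 13.
#' @param interval_minutes sampling interval; default 30.
#' @param mean_air daily-mean surface temperature, degrees C; default 3.1.
#' @param diurnal_amplitude half peak-to-trough amplitude of the base
#'   sinusoid, degrees C; default 4.5.
#' @param spike_prob probability that a given day is a clear radiative-spike
#'   day; default 0.4.
#' @param spike_magnitude peak added warming on spike days, degrees C;
#'   default 8.
#' @param spike_sd temporal width (hours) of the midday spike; default 1.2.
#' @param peak_hour hour of day at which base cycle and spikes peak;
#'   default 12.5.
#' @param buffering moisture buffering factor in \[0, 1\]; default 0 (dry).
#' @param noise_sd Gaussian noise sd, degrees C; default 1.2.
#' @param seed integer seed; the generator is deterministic given it.
#' @param start first timestamp; default "2003-01-16 00:00" UTC.
#' @param species,site,moisture metadata for the trace.
#' @return A [temperature_trace()] with a `truth` attribute.
#' @export
simulate_temperature_trace <- function(days = 13, interval_minutes = 30,
                                       mean_air = 3.1,
                                       diurnal_amplitude = 4.5,
                                       spike_prob = 0.4, spike_magnitude = 8,
                                       spike_sd = 1.2, peak_hour = 12.5,
                                       buffering = 0, noise_sd = 1.2,
                                       seed = 1,
                                       start = "2003-01-16 00:00",
                                       species = "synthetic",
                                       site = "synthetic",
                                       moisture = "unknown") {
  if (days < 1) stopf("days must be >= 1")
  check_number(interval_minutes, "interval_minutes", positive = TRUE, len = 1)
  check_number(buffering, "buffering", len = 1)
  if (buffering < 0 || buffering > 1) stopf("buffering must be in [0, 1]")
  if (spike_prob < 0 || spike_prob > 1) stopf("spike_prob must be in [0, 1]")
  check_number(noise_sd, "noise_sd", nonneg = TRUE, len = 1)
  check_number(spike_magnitude, "spike_magnitude", nonneg = TRUE, len = 1)
  check_number(diurnal_amplitude, "diurnal_amplitude", nonneg = TRUE, len = 1)

  t0 <- as.POSIXct(start, tz = "UTC")
  n_per_day <- as.integer(round(24 * 60 / interval_minutes))
  n <- days * n_per_day
  ts <- t0 + seq(0, by = interval_minutes * 60, length.out = n)
  hour <- (seq(0, by = interval_minutes / 60, length.out = n)) %% 24
  day <- rep(seq_len(days), each = n_per_day)

  damp <- 1 - buffering
  base <- mean_air + diurnal_amplitude * damp *
    cos(2 * pi * (hour - peak_hour) / 24)
  temp <- with_seed(derive_seed(seed, "temperature_trace"), {
    spike_day <- stats::runif(days) < spike_prob
    bump <- spike_magnitude * damp *
      exp(-(hour - peak_hour)^2 / (2 * spike_sd^2)) *
      as.numeric(spike_day[day])
    base + bump + stats::rnorm(n, 0, noise_sd)
  })

  out <- temperature_trace(ts, temp, sensor_id = "sim",
                           species = species, site = site,
                           moisture = moisture)
  attr(out, "truth") <- list(
    scenario_name = "temperature_trace",
    days = days, interval_minutes = interval_minutes, mean_air = mean_air,
    diurnal_amplitude = diurnal_amplitude, spike_prob = spike_prob,
    spike_magnitude = spike_magnitude, spike_sd = spike_sd,
    peak_hour = peak_hour, buffering = buffering, noise_sd = noise_sd,
    seed = seed
  )
  out
}

#' Analytic expected fractions for the trace generator
#'
#' Marginalising over the spike Bernoulli and Gaussian noise, computes the
#' expected percent of records strictly below `low` and strictly above
#' `high` for a given generator parameterisation; the closed-form
#' counterpart to [fraction_time_outside()] on simulated traces.
#'
#' @inheritParams simulate_temperature_trace
#' @param low,high thresholds in degrees C.
#' @param n_grid hour-of-day integration grid size.
#' @return Named vector `c(percent_below, percent_above)`.
#' @export
expected_fraction_outside <- function(mean_air = 3.1, diurnal_amplitude = 4.5,
                                      spike_prob = 0.4, spike_magnitude = 8,
                                      spike_sd = 1.2, peak_hour = 12.5,
                                      buffering = 0, noise_sd = 1.2,
                                      low = 4, high = 14, n_grid = 4801) {
  h <- seq(0, 24, length.out = n_grid)[-n_grid]
  damp <- 1 - buffering
  base <- mean_air + diurnal_amplitude * damp * cos(2 * pi * (h - peak_hour) / 24)
  bump <- spike_magnitude * damp * exp(-(h - peak_hour)^2 / (2 * spike_sd^2))
  p <- spike_prob
  sd <- max(noise_sd, 1e-12)
  below <- mean(p * stats::pnorm((low - (base + bump)) / sd) +
                (1 - p) * stats::pnorm((low - base) / sd))
  above <- mean(p * stats::pnorm((high - (base + bump)) / sd, lower.tail = FALSE) +
                (1 - p) * stats::pnorm((high - base) / sd, lower.tail = FALSE))
  c(percent_below = 100 * below, percent_above = 100 * above)
}

#' Simulate a rapid light-response curve
#'
#' Exact model values at the requested PPFD levels plus optional Gaussian
#' noise; the true (AQE, ETRmax) are recorded in the `truth` attribute.
#'
#' @param model `"rational"` or `"waiting_in_line"`.
#' @param aqe,etr_max true model parameters (> 0).
#' @param ppfd_levels strictly increasing non-negative PPFD levels (>= 4).
#' @param noise_sd Gaussian noise sd on ETR; default 0.
#' @param seed integer seed.
#' @param replicate_id,temperature metadata for the curve.
#' @return A [light_curve()] with a `truth` attribute.
#' @export
simulate_light_curve <- function(model = c("rational", "waiting_in_line"),
                                 aqe, etr_max,
                                 ppfd_levels = c(0, 25, 50, 100, 200, 400,
                                                 800, 1200, 1600),
                                 noise_sd = 0, seed = 1,
                                 replicate_id = "sim", temperature = NA_real_) {
  model <- match.arg(model)
  fn <- switch(model, rational = rational_model,
               waiting_in_line = waiting_in_line_model)
  mu <- fn(ppfd_levels, aqe, etr_max)
  etr <- if (noise_sd > 0) {
    with_seed(derive_seed(seed, "light_curve"),
              mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  out <- light_curve(ppfd_levels, etr, replicate_id = replicate_id,
                     temperature = temperature)
  attr(out, "truth") <- list(
    scenario_name = "light_curve", model = model, aqe = aqe,
    etr_max = etr_max, ppfd_levels = ppfd_levels, noise_sd = noise_sd,
    seed = seed
  )
  out
}

#' Simulate an internally consistent gas-exchange observation
#'
#' Forward construction that enforces the variable-J identities: given a
#' true mesophyll conductance `gm_true`, chloroplastic CO2 `cc`, compensation
#' point `gamma_star`, light respiration `r_light`, and ambient CO2 `ca`,
#'
#' * `a_sat = gm_true * (ca - cc)`
#' * `etr = 4 * (a_sat + r_light) * (cc + 2 * gamma_star) / (cc - gamma_star)`
#'
#' so that on noiseless data [mesophyll_conductance()] recovers `gm_true`
#' exactly. Optional Gaussian noise perturbs `a_sat` and `etr`.
#'
#' @param gm_true true mesophyll conductance, mol m-2 s-1 (> 0).
#' @param cc chloroplastic CO2, umol mol-1; must exceed `gamma_star`.
#' @param gamma_star compensation point, umol mol-1 (>= 0).
#' @param r_light light respiration magnitude, umol m-2 s-1 (>= 0).
#' @param ca ambient CO2, umol mol-1; default 400 (must exceed `cc` for a
#'   positive assimilation flux).
#' @param noise_sd relative Gaussian noise on `a_sat` and `etr`; default 0.
#' @param seed integer seed.
#' @param temperature metadata, degrees C.
#' @return List of class `gas_exchange_observation` with `a_sat`, `etr`,
#'   `ca`, `r_light`, `gamma_star`, `temperature` and a `truth` attribute.
#' @examples
#' obs <- simulate_gas_exchange(gm_true = 0.05, cc = 200, gamma_star = 40,
#'                              r_light = 1, ca = 300)
#' obs$a_sat # 5
#' obs$etr   # 42
#' @export
simulate_gas_exchange <- function(gm_true, cc, gamma_star, r_light,
                                  ca = 400, noise_sd = 0, seed = 1,
                                  temperature = NA_real_) {
  check_number(gm_true, "gm_true", positive = TRUE, len = 1)
  check_number(cc, "cc", positive = TRUE, len = 1)
  check_number(gamma_star, "gamma_star", nonneg = TRUE, len = 1)
  check_number(r_light, "r_light", nonneg = TRUE, len = 1)
  check_number(ca, "ca", positive = TRUE, len = 1)
  if (cc <= gamma_star)
    stopf("cc must exceed gamma_star (else gross assimilation is negative)")
  if (ca <= cc)
    stopf("ca must exceed cc for a positive diffusion gradient")
  a_sat <- gm_true * (ca - cc)
  etr <- 4 * (a_sat + r_light) * (cc + 2 * gamma_star) / (cc - gamma_star)
  if (noise_sd > 0) {
    eps <- with_seed(derive_seed(seed, "gas_exchange"),
                     stats::rnorm(2, 0, noise_sd))
    a_sat <- a_sat * (1 + eps[1])
    etr <- etr * (1 + eps[2])
  }
  structure(
    list(a_sat = a_sat, etr = etr, ca = ca, r_light = r_light,
         gamma_star = gamma_star, temperature = temperature),
    truth = list(scenario_name = "gas_exchange", gm_true = gm_true, cc = cc,
                 gamma_star = gamma_star, r_light = r_light, ca = ca,
                 noise_sd = noise_sd, seed = seed),
    class = "gas_exchange_observation"
  )
}

#' Simulate a response-versus-temperature series from a known cubic
#'
#' @param cubic_coeffs numeric c(c0, c1, c2, c3).
#' @param t_grid temperatures (>= 4 points), degrees C.
#' @param noise_sd Gaussian noise sd on the response; default 0.
#' @param seed integer seed.
#' @param response_name,replicate_id metadata.
#' @return A [thermal_series()] with a `truth` attribute.
#' @export
simulate_thermal_response <- function(cubic_coeffs, t_grid, noise_sd = 0,
                                      seed = 1, response_name = "response",
                                      replicate_id = "sim") {
  check_number(cubic_coeffs, "cubic_coeffs", len = 4)
  check_number(t_grid, "t_grid")
  if (length(t_grid) < 4L) stopf("t_grid needs >= 4 points")
  mu <- eval_cubic(cubic_coeffs, t_grid)
  y <- if (noise_sd > 0) {
    with_seed(derive_seed(seed, "thermal_response"),
              mu + stats::rnorm(length(mu), 0, noise_sd))
  } else mu
  out <- thermal_series(t_grid, y, response_name = response_name,
                        replicate_id = replicate_id)
  attr(out, "truth") <- list(
    scenario_name = "thermal_response", cubic_coeffs = cubic_coeffs,
    t_grid = t_grid, noise_sd = noise_sd, seed = seed
  )
  out
}

#' Simulate a full synthetic study bundle
#'
#' Generates, for one synthetic species, everything [run_pipeline()]
#' consumes: a Casey-like temperature trace, per-replicate ETR light curves
#' across a temperature grid (ETRmax following a known cubic with optimum
#' near 24 degrees C), a gas-exchange table consistent with a known gm(T),
#' and an Asat-versus-temperature table from a known cubic. All truths are
#' recorded.
#'
#' @param seed integer master seed.
#' @param n_replicates replicates per temperature for curve fits; default 3.
#' @param t_grid measurement temperature grid, degrees C; default
#'   `seq(5, 35, 5)`.
#' @param dir optional directory: when given, the bundle is also written as
#'   the CSV/JSON files the pipeline readers consume.
#' @return List with `trace`, `light_curves` (long data frame),
#'   `asat_table`, `gas_exchange`, `truth`.
#' @export
simulate_study <- function(seed = 1, n_replicates = 3,
                           t_grid = seq(5, 35, 5), dir = NULL) {
  # known cubics with interior optima in the low/mid 20s, values in the
  # range reported for polar mosses (Asat a few umol m-2 s-1, ETRmax tens)
  asat_cubic <- c(-4.0, 0.95, -0.021, -0.00005)
  etrmax_cubic <- c(5, 4.2, -0.04, -0.0012)
  gm_at <- function(t) 0.005 + 0.002 * pmax(t - 5, 0)  # rises with T
  r_light <- 1
  gamma_star_true <- 40
  rd5 <- 4  # comparable to the Asat peak (~6): cold mosses respire near A

  trace <- simulate_temperature_trace(seed = derive_seed(seed, "study_trace"))

  lc_rows <- list()
  for (t in t_grid) {
    emax <- max(eval_cubic(etrmax_cubic, t), 5)
    for (r in seq_len(n_replicates)) {
      id <- sprintf("rep%d", r)
      cv <- simulate_light_curve("rational", aqe = 0.3, etr_max = emax,
                                 noise_sd = 1,
                                 seed = derive_seed(seed, paste0("lc", t, id)),
                                 replicate_id = id, temperature = t)
      lc_rows[[paste(t, id)]] <- data.frame(
        replicate_id = id, temperature_c = t, ppfd = cv$ppfd, etr = cv$etr)
    }
  }
  light_curves <- do.call(rbind, lc_rows)
  rownames(light_curves) <- NULL

  asat_rows <- list()
  for (r in seq_len(n_replicates)) {
    id <- sprintf("rep%d", r)
    ser <- simulate_thermal_response(asat_cubic, t_grid, noise_sd = 0.15,
                                     seed = derive_seed(seed, paste0("asat", id)),
                                     response_name = "Asat", replicate_id = id)
    asat_rows[[id]] <- data.frame(replicate_id = id,
                                  temperature_c = ser$temperature,
                                  response = ser$response)
  }
  asat_table <- do.call(rbind, asat_rows)
  rownames(asat_table) <- NULL

  ge_rows <- list()
  for (t in t_grid) {
    cc <- 180 + 2 * (t - 20)
    obs <- simulate_gas_exchange(gm_at(t), cc, gamma_star_true, r_light,
                                 ca = 400, noise_sd = 0,
                                 seed = derive_seed(seed, paste0("ge", t)),
                                 temperature = t)
    # back out plausible fluorescence channels consistent with the ETR
    # (alpha-beta 0.42, PPFD 800): phi = etr / (ppfd * ab)
    phi <- min(obs$etr / (800 * 0.42), 0.85)
    fm_prime <- 1200
    fs <- fm_prime * (1 - phi)
    ge_rows[[as.character(t)]] <- data.frame(
      replicate_id = "rep1", species = "synthetic", temperature_c = t,
      ca_umol_mol = obs$ca, ppfd = 800, a_n = obs$a_sat,
      fs = fs, fm_prime = fm_prime, f0 = 300, fm = 1500
    )
  }
  gas_exchange <- do.call(rbind, ge_rows)
  rownames(gas_exchange) <- NULL

  truth <- list(
    scenario_name = "study", seed = seed, asat_cubic = asat_cubic,
    etrmax_cubic = etrmax_cubic, aqe = 0.3, gamma_star = gamma_star_true,
    r_light = r_light, r_dark_at_5 = rd5, alpha_beta = 0.42,
    gm_intercept = 0.005, gm_slope = 0.002, t_grid = t_grid,
    trace_truth = synthetic_truth(trace)
  )

  out <- list(trace = trace, light_curves = light_curves,
              asat_table = asat_table, gas_exchange = gas_exchange,
              truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_trace_csv(trace, file.path(dir, "trace.csv"))
    utils::write.csv(light_curves, file.path(dir, "light_curves.csv"),
                     row.names = FALSE)
    utils::write.csv(asat_table, file.path(dir, "asat.csv"), row.names = FALSE)
    utils::write.csv(gas_exchange, file.path(dir, "gas_exchange.csv"),
                     row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
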