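# End-to-end orchestration: microclimate -> light curves -> thermal fits ->
# mesophyll conductance -> carbon balance, from a validated plain-text
# config, with structured logging and reproducible, stamped outputs.

#' Build a validated pipeline run configuration
#'
#' Scientifically load-bearing constants have no defaults: `s_co` (the
#' Rubisco specificity factor, which sets Gamma* via [gamma_star()]) must
#' always be supplied. Paths are checked at validation time.
#'
#' @param trace_csv,light_curves_csv,asat_csv,gas_exchange_csv input paths
#'   (see the reader functions for the expected columns).
#' @param s_co Rubisco specificity factor (required, > 0).
#' @param o2_ubar oxygen partial pressure for Gamma*, ubar; default 210000
#'   (ambient).
#' @param alpha_beta alpha-beta used for ETR in the gas-exchange branch;
#'   a number or [absorptance_factor()]; default the provisional 0.42.
#' @param r_light light-respiration magnitude, umol m-2 s-1.
#' @param r_dark_at_5 dark respiration at 5 degrees C, umol m-2 s-1.
#' @param bin_width histogram bin width, degrees C; default 2.
#' @param balance_threshold sub-threshold temperature for the carbon
#'   balance, degrees C; default 4.
#' @param scenario_fractions respiration fractions in (0, 1]; default
#'   c(0.50, 0.333, 0.25, 0.05).
#' @param seed integer seed stamped into outputs.
#' @param out_dir output directory (created if needed); `NULL` for no files.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(trace_csv, light_curves_csv, asat_csv,
                       gas_exchange_csv, s_co,
                       o2_ubar = 210000, alpha_beta = 0.42,
                       r_light = 0, r_dark_at_5 = 0,
                       bin_width = 2, balance_threshold = 4,
                       scenario_fractions = c(0.50, 0.333, 0.25, 0.05),
                       seed = 1, out_dir = NULL) {
  if (missing(s_co) || is.null(s_co))
    stopf("`s_co` (Rubisco specificity factor) is required and has no default")
  check_number(s_co, "s_co", positive = TRUE, len = 1)
  check_number(o2_ubar, "o2_ubar", positive = TRUE, len = 1)
  check_number(scenario_fractions, "scenario_fractions")
  if (any(scenario_fractions <= 0 | scenario_fractions > 1))
    stopf("scenario_fractions must be in (0, 1]")
  check_number(bin_width, "bin_width", positive = TRUE, len = 1)
  check_number(balance_threshold, "balance_threshold", len = 1)
  check_number(r_light, "r_light", nonneg = TRUE, len = 1)
  check_number(r_dark_at_5, "r_dark_at_5", nonneg = TRUE, len = 1)
  paths <- c(trace_csv = trace_csv, light_curves_csv = light_curves_csv,
             asat_csv = asat_csv, gas_exchange_csv = gas_exchange_csv)
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]]))
      stopf("config path `%s` does not exist: %s", nm, paths[[nm]])
  }
  structure(
    list(trace_csv = trace_csv, light_curves_csv = light_curves_csv,
         asat_csv = asat_csv, gas_exchange_csv = gas_exchange_csv,
         s_co = s_co, o2_ubar = o2_ubar,
         alpha_beta = as_alpha_beta(alpha_beta),
         r_light = r_light, r_dark_at_5 = r_dark_at_5,
         bin_width = bin_width, balance_threshold = balance_threshold,
         scenario_fractions = scenario_fractions,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory. Validation (including the
#' required `s_co`) happens before any computation.
#'
#' @param path YAML config path.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base, p)
  }
  args <- list(
    trace_csv = resolve(y$trace_csv),
    light_curves_csv = resolve(y$light_curves_csv),
    asat_csv = resolve(y$asat_csv),
    gas_exchange_csv = resolve(y$gas_exchange_csv),
    s_co = y$s_co
  )
  for (k in c("o2_ubar", "alpha_beta", "r_light", "r_dark_at_5", "bin_width",
              "balance_threshold", "scenario_fractions", "seed", "out_dir"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end analysis: bins the temperature trace into a
#' frequency-of-time histogram, fits every ETR light curve and the
#' per-replicate ETRmax and Asat temperature cubics with their optima,
#' estimates mesophyll conductance (with limitation partitioning) across
#' temperature, computes the 15-25 degree Q10 of gm, and runs the
#' carbon-balance respiration scenarios. Every output table carries the
#' config hash and seed; a structured log records dropped records,
#' singularity-flagged observations and boundary-flagged optima. Any stage
#' failure aborts with the stage name.
#'
#' @param config a [run_config()] or path to a YAML config.
#' @return List of class `pipeline_result`: `histogram`,
#'   `outside` (percent below/above thresholds), `light_curve_fits`,
#'   `etrmax_topt` (per-replicate optima + summary), `asat_topt`,
#'   `gas_exchange` (per-temperature gm/limitations table), `q10_gm`,
#'   `balance` (scenario table), `log`, `stamp`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage `%s` failed: %s", name, conditionMessage(e)))
  }

  # --- microclimate ---
  trace <- stage("microclimate", read_logger_csv(config$trace_csv))
  hist <- stage("microclimate",
                bin_temperature_frequency(trace, config$bin_width))
  outside <- fraction_time_outside(trace, low = config$balance_threshold)
  log$n_trace_records <- nrow(trace)

  # --- light curves ---
  lc <- stage("lightcurves", {
    d <- utils::read.csv(config$light_curves_csv)
    fit_light_curve_table(d)
  })
  log$n_light_curves <- nrow(lc)
  log$n_unconverged_curves <- sum(!lc$converged)

  # --- thermal optima ---
  etr_topt <- stage("thermal", {
    fit_thermal_table(
      data.frame(replicate_id = lc$replicate_id,
                 temperature_c = lc$temperature_c, response = lc$etr_max),
      response_name = "ETRmax")
  })
  asat_raw <- stage("thermal", utils::read.csv(config$asat_csv))
  asat_topt <- stage("thermal", fit_thermal_table(asat_raw, "Asat"))
  log$n_boundary_topt <- sum(etr_topt$per_replicate$boundary) +
    sum(asat_topt$per_replicate$boundary)

  # --- mesophyll conductance ---
  gs <- gamma_star(config$o2_ubar, config$s_co)
  ge <- stage("gm", {
    d <- utils::read.csv(config$gas_exchange_csv)
    gas_exchange_table(d, gamma_star = gs, alpha_beta = config$alpha_beta,
                       r_light = config$r_light)
  })
  log$n_gm_singular <- attr(ge, "report")$n_singular

  q10_gm <- stage("gm", {
    gm15 <- ge$gm[abs(ge$temperature_c - 15) < 2.5 & is.finite(ge$gm)]
    gm25 <- ge$gm[abs(ge$temperature_c - 25) < 2.5 & is.finite(ge$gm)]
    if (length(gm15) && length(gm25) && mean(gm15) > 0 && mean(gm25) > 0)
      unname(q10(mean(gm15), mean(gm25), 15, 25)) else NA_real_
  })

  # --- carbon balance ---
  balance <- stage("balance", {
    pooled <- fit_cubic(thermal_series(asat_raw$temperature_c,
                                       asat_raw$response, "Asat"))
    resp <- assimilation_response(pooled, r_dark_at_5 = config$r_dark_at_5)
    run_scenarios(hist, resp, fractions = config$scenario_fractions,
                  threshold = config$balance_threshold)
  })

  stamp <- list(
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    seed = config$seed
  )

  result <- structure(
    list(histogram = hist, outside = outside, light_curve_fits = lc,
         etrmax_topt = etr_topt[c("per_replicate", "summary")],
         asat_topt = asat_topt[c("per_replicate", "summary")],
         gas_exchange = ge, q10_gm = q10_gm, balance = balance,
         log = log, stamp = stamp),
    class = "pipeline_result"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, name) {
      p <- file.path(config$out_dir, name)
      con <- file(p, "w")
      writeLines(sprintf("# config_hash=%s seed=%d",
                         stamp$config_hash, stamp$seed), con)
      utils::write.csv(d, con, row.names = FALSE)
      close(con)
    }
    wr(as.data.frame(hist), "histogram.csv")
    wr(lc, "light_curve_fits.csv")
    wr(etr_topt$per_replicate, "etrmax_topt.csv")
    wr(asat_topt$per_replicate, "asat_topt.csv")
    wr(as.data.frame(ge), "gas_exchange.csv")
    wr(as.data.frame(result$balance), "carbon_balance.csv")
    jsonlite::write_json(c(stamp, log), file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  trace: %d records; %.1f%% below threshold, %.1f%% above 14\n",
              x$log$n_trace_records, x$outside["percent_below"],
              x$outside["percent_above"]))
  cat(sprintf("  light curves: %d fits (%d unconverged)\n",
              x$log$n_light_curves, x$log$n_unconverged_curves))
  cat(sprintf("  ETRmax Topt: %.1f +/- %.1f degC (n = %d)\n",
              x$etrmax_topt$summary$mean_t_opt, x$etrmax_topt$summary$se_t_opt,
              x$etrmax_topt$summary$n))
  cat(sprintf("  Asat Topt: %.1f +/- %.1f degC; gm Q10(15-25) = %.3g\n",
              x$asat_topt$summary$mean_t_opt, x$asat_topt$summary$se_t_opt,
              x$q10_gm))
  cat(sprintf("  gm singularity-flagged observations: %d\n", x$log$n_gm_singular))
  cat("  carbon balance:\n")
  print.data.frame(as.data.frame(x$balance), row.names = FALSE, digits = 4)
  invisible(x)
}
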