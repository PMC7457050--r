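# Carbon-balance engine: combine a temperature-frequency histogram with an
# assimilation temperature response and a sub-threshold respiration scenario
# to estimate percent carbon fixed versus lost.

#' Assimilation temperature response for the carbon-balance model
#'
#' Bundles a fitted Asat-versus-temperature cubic with the temperature range
#' over which it was measured and the dark-respiration magnitude at 5
#' degrees C (the anchor for sub-threshold respiration scenarios). Outside
#' `valid_range` the cubic is clamped to its endpoint values, never
#' extrapolated (cubics diverge).
#'
#' @param cubic a [fit_cubic()] result for Asat versus temperature.
#' @param valid_range `c(low, high)` degrees C over which the cubic may be
#'   evaluated; defaults to the fit domain (conventionally 5-35).
#' @param r_dark_at_5 dark respiration magnitude at 5 degrees C,
#'   umol CO2 m-2 s-1 (>= 0).
#' @return An object of class `assimilation_response`.
#' @export
assimilation_response <- function(cubic, valid_range = NULL, r_dark_at_5) {
  stopifnot(inherits(cubic, "cubic_thermal_fit"))
  if (is.null(valid_range)) valid_range <- cubic$domain
  check_number(valid_range, "valid_range", len = 2)
  if (valid_range[1] >= valid_range[2]) stopf("valid_range must be increasing")
  if (valid_range[1] < cubic$domain[1] - 1e-9 ||
      valid_range[2] > cubic$domain[2] + 1e-9)
    stopf("valid_range must lie within the cubic's fit domain")
  check_number(r_dark_at_5, "r_dark_at_5", nonneg = TRUE, len = 1)
  structure(list(cubic = cubic, valid_range = valid_range,
                 r_dark_at_5 = r_dark_at_5),
            class = "assimilation_response")
}

#' @export
print.assimilation_response <- function(x, ...) {
  cat(sprintf("<assimilation_response> valid on [%g, %g] degC, RD(5) = %.3g\n",
              x$valid_range[1], x$valid_range[2], x$r_dark_at_5))
  invisible(x)
}

#' Assign per-bin assimilation under a respiration scenario
#'
#' For each histogram bin: if the bin midpoint is below the threshold
#' (default 4 degrees C), assimilation is negative and equals
#' `-fraction_rd5 * RD(5)` (partial inhibition of respiration in the cold);
#' otherwise the Asat cubic is evaluated at the bin midpoint, clamped to the
#' valid-range endpoints. The weighted contribution is
#' `a_sat_t = a_sat * frequency`.
#'
#' @param hist a `temperature_histogram` (see [bin_temperature_frequency()]).
#' @param resp an [assimilation_response()].
#' @param fraction_rd5 fraction of RD(5) that persists below the threshold,
#'   in (0, 1].
#' @param threshold temperature below which assimilation is treated as
#'   negative, degrees C (default 4).
#' @return Data frame: `bin_mid`, `frequency_pct`, `a_sat`, `a_sat_t`,
#'   `clamped` (logical: midpoint outside the valid range).
#' @export
assign_bin_assimilation <- function(hist, resp, fraction_rd5, threshold = 4) {
  stopifnot(inherits(hist, "temperature_histogram"),
            inherits(resp, "assimilation_response"))
  check_number(fraction_rd5, "fraction_rd5", len = 1)
  if (fraction_rd5 <= 0 || fraction_rd5 > 1)
    stopf("fraction_rd5 must be in (0, 1]")
  check_number(threshold, "threshold", len = 1)
  if (!nrow(hist)) stopf("empty histogram")
  mid <- (hist$bin_low + hist$bin_high) / 2
  t_eval <- pmin(pmax(mid, resp$valid_range[1]), resp$valid_range[2])
  a_sat <- predict(resp$cubic, t_eval)
  sub <- mid < threshold
  a_sat[sub] <- -fraction_rd5 * resp$r_dark_at_5
  data.frame(
    bin_mid = mid, frequency_pct = hist$frequency_pct,
    a_sat = a_sat, a_sat_t = a_sat * hist$frequency_pct,
    clamped = !sub & (mid < resp$valid_range[1] | mid > resp$valid_range[2])
  )
}

#' Percent carbon fixed versus lost
#'
#' From frequency-weighted per-bin contributions:
#' `pct_fixed = sum(positive) / (sum(positive) + |sum(negative)|) * 100`,
#' with `pct_lost` its complement. The ratio is invariant to rescaling all
#' frequencies.
#'
#' @param per_bin data frame from [assign_bin_assimilation()] (needs column
#'   `a_sat_t`), or a bare numeric vector of contributions.
#' @return Named vector `c(pct_fixed, pct_lost)`, summing to 100.
#' @examples
#' carbon_balance(c(3, 1, -1)) # 80 / 20
#' @export
carbon_balance <- function(per_bin) {
  x <- if (is.data.frame(per_bin)) per_bin$a_sat_t else per_bin
  check_number(x, "a_sat_t")
  if (!length(x)) stopf("no bins")
  pos <- sum(x[x > 0])
  neg <- abs(sum(x[x < 0]))
  if (pos + neg == 0) stopf("all contributions zero: carbon balance undefined")
  c(pct_fixed = 100 * pos / (pos + neg),
    pct_lost = 100 * neg / (pos + neg))
}

#' Run carbon-balance scenarios over respiration fractions
#'
#' One [carbon_balance()] per respiration fraction (the canonical set is
#' 50%, 33.3%, 25% and 5% of RD at 5 degrees C). Fixation percent is
#' monotone non-increasing in the fraction: the stronger the residual
#' respiration, the worse the balance.
#'
#' @param hist a `temperature_histogram`.
#' @param resp an [assimilation_response()].
#' @param fractions respiration fractions in (0, 1].
#' @param threshold sub-threshold temperature, degrees C (default 4).
#' @param species optional label carried into the output.
#' @return An object of class `carbon_balance_result`: data frame
#'   `species, fraction_rd, pct_lost, pct_fixed` with the per-bin detail in
#'   attribute `per_bin` (a named list of data frames).
#' @export
run_scenarios <- function(hist, resp, fractions = c(0.50, 0.333, 0.25, 0.05),
                          threshold = 4, species = "") {
  check_number(fractions, "fractions")
  if (any(fractions <= 0 | fractions > 1))
    stopf("fractions must be in (0, 1]")
  detail <- list()
  rows <- lapply(fractions, function(f) {
    pb <- assign_bin_assimilation(hist, resp, f, threshold)
    detail[[sprintf("%g", f)]] <<- pb
    bal <- carbon_balance(pb)
    data.frame(species = species, fraction_rd = f,
               pct_lost = unname(bal["pct_lost"]),
               pct_fixed = unname(bal["pct_fixed"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, per_bin = detail,
            class = c("carbon_balance_result", "data.frame"))
}

#' @export
print.carbon_balance_result <- function(x, ...) {
  cat("<carbon_balance_result>\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
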