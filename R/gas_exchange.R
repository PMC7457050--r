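# Variable-J mesophyll conductance for astomatous bryophytes, alpha-beta
# and light-respiration calibration from low-O2 light curves, and
# limitation partitioning.

#' Chloroplastic CO2 compensation point (Gamma*)
#'
#' `Gamma* = 0.5 * O / S_C/O`, from the oxygen partial pressure and the
#' Rubisco specificity factor. Units follow the oxygen input (ubar in,
#' ubar out); keeping O and `S_C/O` on a consistent basis is the caller's
#' responsibility. `S_C/O` has no default: it is a measured, species-group
#' specific quantity (for bryophytes, an average over published values) and
#' must be supplied explicitly.
#'
#' @param o2 oxygen partial pressure (e.g. 210000 ubar ambient; a sub-1%
#'   value for low-O2 calibration runs), > 0.
#' @param s_co Rubisco CO2/O2 specificity factor, > 0, consistent with `o2`.
#' @return Gamma* in the units of `o2` (per mole basis).
#' @examples
#' gamma_star(210000, 2625) # 40
#' @export
gamma_star <- function(o2, s_co) {
  check_number(o2, "o2", positive = TRUE)
  check_number(s_co, "s_co", positive = TRUE)
  0.5 * o2 / s_co
}

#' Variable-J mesophyll conductance
#'
#' Harley-type estimate adapted for astomatous moss gametophytes, where the
#' ambient CO2 concentration Ca replaces the intercellular Ci:
#'
#' `gm = Asat / (Ca - Gamma* * (ETR + 8 (Asat + RL)) / (ETR - 4 (Asat + RL)))`
#'
#' The bracket term is the chloroplastic CO2 concentration `Cc` (equivalently
#' `Ca - Asat / gm`). Mesophyll versus biochemical limitations are then
#' partitioned with `A/Cc` as the proxy for the slope dA/dCc (see
#' [limitation_partition()]).
#'
#' The denominator `ETR - 4 (Asat + RL)` must be positive: electron
#' transport has to exceed four times the gross carboxylation term. At or
#' below that pole (typical of cold-temperature observations) the estimate
#' is undefined and the observation raises a singularity error; callers
#' building temperature curves should catch it and flag the record.
#'
#' @param a_sat net CO2 assimilation at saturating light, umol m-2 s-1.
#' @param r_light respiration in the light (magnitude, >= 0), umol m-2 s-1;
#'   dark respiration may be supplied instead if RL was not calibrated.
#' @param ca ambient CO2 concentration, umol mol-1 (> 0).
#' @param etr electron transport rate, umol electrons m-2 s-1.
#' @param gamma_star CO2 compensation point from [gamma_star()], umol mol-1.
#' @return An object of class `mesophyll_estimate`: list with `gm`, `cc`,
#'   `gamma_star`, `lm`, `lb`, `flags` (character vector; empty when clean).
#' @examples
#' est <- mesophyll_conductance(a_sat = 5, r_light = 1, ca = 300,
#'                              etr = 42, gamma_star = 40)
#' est$gm # 0.05
#' @export
mesophyll_conductance <- function(a_sat, r_light, ca, etr, gamma_star) {
  check_number(a_sat, "a_sat", len = 1)
  check_number(r_light, "r_light", nonneg = TRUE, len = 1)
  check_number(ca, "ca", positive = TRUE, len = 1)
  check_number(etr, "etr", nonneg = TRUE, len = 1)
  check_number(gamma_star, "gamma_star", nonneg = TRUE, len = 1)
  demand <- 4 * (a_sat + r_light)
  if (etr <= demand)
    stopf(paste0("variable-J singularity: ETR (%.4g) must exceed ",
                 "4*(Asat + RL) = %.4g; observation unusable"), etr, demand)
  cc <- gamma_star * (etr + 8 * (a_sat + r_light)) / (etr - demand)
  gm <- a_sat / (ca - cc)
  flags <- character(0)
  if (!is.finite(gm)) flags <- c(flags, "gm_nonfinite")
  else if (gm < 0) flags <- c(flags, "gm_negative")
  else if (gm == 0) flags <- c(flags, "gm_zero")
  lm_lb <- if (is.finite(gm) && gm > 0 && cc > 0 && a_sat > 0) {
    limitation_partition(gm, a_sat / cc)
  } else {
    flags <- c(flags, "limitations_undefined")
    c(lm = NA_real_, lb = NA_real_)
  }
  structure(
    list(gm = gm, cc = cc, gamma_star = gamma_star,
         a_sat = a_sat, r_light = r_light, ca = ca, etr = etr,
         lm = unname(lm_lb["lm"]), lb = unname(lm_lb["lb"]),
         flags = flags),
    class = "mesophyll_estimate"
  )
}

#' @export
print.mesophyll_estimate <- function(x, ...) {
  cat(sprintf("<mesophyll_estimate> gm = %.4g mol m-2 s-1, Cc = %.4g umol mol-1\n",
              x$gm, x$cc))
  if (is.finite(x$lm))
    cat(sprintf("  limitations: mesophyll %.3f / biochemical %.3f\n", x$lm, x$lb))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Partition mesophyll versus biochemical limitation
#'
#' Quantitative limitation analysis (Grassi-Magnani style, reduced to the
#' stomata-free case): `lm = s / (gm + s)` and `lb = gm / (gm + s)` where
#' `s` is the slope dA/dCc (proxied by `A/Cc` at the operating point). The
#' two fractions sum to one.
#'
#' @param gm mesophyll conductance, mol m-2 s-1 (> 0). Vectorised.
#' @param da_dcc slope of assimilation versus chloroplastic CO2, mol m-2 s-1
#'   (> 0). Vectorised.
#' @return Named vector (or 2-column matrix for vector input) with `lm`
#'   (mesophyll/diffusional fraction) and `lb` (biochemical fraction).
#' @examples
#' limitation_partition(0.05, 0.025) # lm = 1/3, lb = 2/3
#' @export
limitation_partition <- function(gm, da_dcc) {
  check_number(gm, "gm", positive = TRUE)
  check_number(da_dcc, "da_dcc", positive = TRUE)
  lm <- da_dcc / (gm + da_dcc)
  lb <- gm / (gm + da_dcc)
  if (length(lm) == 1L) c(lm = lm, lb = lb) else cbind(lm = lm, lb = lb)
}

#' Apparent quantum yield of CO2 fixation
#'
#' `phiCO2 = (AN + RL) / PPFD`: gross assimilation per incident photon,
#' used against phiPSII to calibrate alpha-beta under non-photorespiratory
#' (low-O2) conditions.
#'
#' @param a_n net CO2 assimilation, umol m-2 s-1. Vectorised.
#' @param r_light light respiration magnitude, umol m-2 s-1 (>= 0).
#' @param ppfd incident PPFD, umol photons m-2 s-1 (> 0).
#' @return Dimensionless yield.
#' @export
phi_co2 <- function(a_n, r_light, ppfd) {
  check_number(a_n, "a_n")
  check_number(r_light, "r_light", nonneg = TRUE)
  check_number(ppfd, "ppfd")
  if (any(ppfd <= 0)) stopf("ppfd must be > 0 for phi_co2")
  (a_n + r_light) / ppfd
}

#' Calibrate alpha-beta from a low-O2 light curve
#'
#' Under non-photorespiratory conditions four electrons are required per CO2
#' fixed, so `alpha-beta = 4 * phiCO2 / phiPSII`. Because the
#' phiPSII-to-phiCO2 ratio can drift with PPFD, the default mode
#' (`"highest_ppfd"`) evaluates the ratio at the highest-PPFD point (the
#' light level at which Asat is measured); the alternative (`"slope"`) takes
#' `4 / slope` of the ordinary regression of phiPSII on phiCO2.
#'
#' @param ppfd PPFD levels, >= 3 points spanning >= 2 levels.
#' @param phi_psii effective PSII yields at each point.
#' @param phi_co2 CO2 yields at each point (see [phi_co2()]).
#' @param mode `"highest_ppfd"` (default) or `"slope"`.
#' @return An [absorptance_factor()] with `source = "calibrated"` and
#'   attributes `mode` and `n_points`.
#' @export
calibrate_alpha_beta <- function(ppfd, phi_psii, phi_co2,
                                 mode = c("highest_ppfd", "slope")) {
  mode <- match.arg(mode)
  check_number(ppfd, "ppfd", nonneg = TRUE)
  check_number(phi_psii, "phi_psii", nonneg = TRUE)
  check_number(phi_co2, "phi_co2")
  n <- length(ppfd)
  if (n < 3L || length(phi_psii) != n || length(phi_co2) != n)
    stopf("alpha-beta calibration needs >= 3 aligned points")
  if (length(unique(ppfd)) < 2L)
    stopf("alpha-beta calibration needs >= 2 distinct PPFD levels")
  ab <- if (mode == "highest_ppfd") {
    i <- which.max(ppfd)
    if (phi_psii[i] <= 0)
      stopf("zero phiPSII at the highest PPFD: cannot calibrate alpha-beta")
    4 * phi_co2[i] / phi_psii[i]
  } else {
    sl <- unname(stats::coef(stats::lm(phi_psii ~ phi_co2))[2])
    if (!is.finite(sl) || sl <= 0)
      stopf("non-positive phiPSII~phiCO2 slope: cannot calibrate alpha-beta")
    4 / sl
  }
  out <- absorptance_factor(ab, source = "calibrated")
  attr(out, "mode") <- mode
  attr(out, "n_points") <- n
  out
}

#' Light respiration from the light-limited range (Yin-type intercept)
#'
#' Regresses net assimilation on one quarter of the fluorescence-derived
#' electron flux, `x = phiPSII * PPFD / 4`, over the light-limited points of
#' a low-O2 light curve, and returns the negative of the intercept: the CO2
#' efflux remaining at zero electron transport, i.e. respiration in the
#' light.
#'
#' @param a_n net assimilation at each point, umol m-2 s-1.
#' @param phi_psii effective PSII yield at each point.
#' @param ppfd PPFD at each point.
#' @param ppfd_cutoff keep only points with `ppfd <= ppfd_cutoff`; `NULL`
#'   (default) keeps the 4 lowest distinct PPFD levels.
#' @return List with `r_light` (magnitude; negative if the intercept was
#'   positive), `slope`, `n_points`.
#' @export
light_respiration <- function(a_n, phi_psii, ppfd, ppfd_cutoff = NULL) {
  check_number(a_n, "a_n")
  check_number(phi_psii, "phi_psii", nonneg = TRUE)
  check_number(ppfd, "ppfd", nonneg = TRUE)
  n <- length(a_n)
  if (length(phi_psii) != n || length(ppfd) != n)
    stopf("a_n, phi_psii and ppfd must be aligned")
  keep <- if (is.null(ppfd_cutoff)) {
    lv <- sort(unique(ppfd))
    ppfd %in% lv[seq_len(min(4L, length(lv)))]
  } else ppfd <= ppfd_cutoff
  if (sum(keep) < 3L)
    stopf("light_respiration needs >= 3 light-limited points (got %d)", sum(keep))
  x <- phi_psii[keep] * ppfd[keep] / 4
  fit <- stats::lm(a_n[keep] ~ x)
  cf <- stats::coef(fit)
  list(r_light = -unname(cf[1]), slope = unname(cf[2]), n_points = sum(keep))
}

#' Run the variable-J pipeline over a gas-exchange table
#'
#' Takes a LI-6800-style table (one row per replicate x temperature:
#' `replicate_id, species, temperature_c, ca_umol_mol, ppfd, a_n, fs,
#' fm_prime, f0, fm`), computes fluorescence parameters and ETR with the
#' supplied alpha-beta, and estimates gm with limitation partitioning.
#' Observations failing the variable-J singularity precondition are retained
#' with `NA` estimates and flag `"singularity"` (the behaviour of
#' cold-temperature records), and counted in the attached report.
#'
#' @param d gas-exchange data frame (columns above).
#' @param gamma_star Gamma* in umol mol-1 (see [gamma_star()]).
#' @param alpha_beta an [absorptance_factor()] or number.
#' @param r_light light-respiration magnitude, scalar or one value per row.
#' @return Data frame with one row per observation: inputs plus `phi_psii`,
#'   `npq`, `fv_fm`, `etr`, `gm`, `cc`, `lm`, `lb`, `flags`; attribute
#'   `report` lists counts of flagged records.
#' @export
gas_exchange_table <- function(d, gamma_star, alpha_beta, r_light) {
  need <- c("replicate_id", "temperature_c", "ca_umol_mol", "ppfd", "a_n",
            "fs", "fm_prime")
  if (!all(need %in% names(d))) stopf("missing gas-exchange columns")
  n <- nrow(d)
  rl <- if (length(r_light) == 1L) rep(r_light, n) else r_light
  if (length(rl) != n) stopf("r_light must be scalar or one per row")
  phi <- phi_psii(d$fs, d$fm_prime)
  et <- electron_transport_rate(phi, d$ppfd, alpha_beta)
  nq <- if (all(c("fm") %in% names(d)) && !anyNA(d$fm)) npq(d$fm, d$fm_prime)
        else rep(NA_real_, n)
  fvfm <- if (all(c("f0", "fm") %in% names(d)) && !anyNA(d$f0) && !anyNA(d$fm))
    fv_over_fm(d$f0, d$fm) else rep(NA_real_, n)
  gm <- cc <- lm_ <- lb_ <- rep(NA_real_, n)
  flags <- character(n)
  for (i in seq_len(n)) {
    est <- tryCatch(
      mesophyll_conductance(d$a_n[i], rl[i], d$ca_umol_mol[i], et[i], gamma_star),
      error = function(e) NULL
    )
    if (is.null(est)) {
      flags[i] <- "singularity"
    } else {
      gm[i] <- est$gm; cc[i] <- est$cc
      lm_[i] <- est$lm; lb_[i] <- est$lb
      flags[i] <- paste(est$flags, collapse = ";")
    }
  }
  out <- cbind(d, phi_psii = phi, npq = nq, fv_fm = fvfm, etr = et,
               gm = gm, cc = cc, lm = lm_, lb = lb_,
               r_light = rl, flags = flags,
               stringsAsFactors = FALSE)
  attr(out, "report") <- list(
    n = n,
    n_singular = sum(flags == "singularity"),
    n_flagged = sum(nzchar(flags))
  )
  out
}
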