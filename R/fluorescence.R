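# Pulse-modulated chlorophyll fluorescence parameters and electron
# transport rate.

#' Absorptance-partitioning factor (alpha-beta)
#'
#' The product of leaf absorptance and the fraction of absorbed quanta
#' reaching PSII, used to scale incident PPFD into the ETR calculation.
#' Carried as a first-class value with provenance: the provisional literature
#' constant 0.42, or a value calibrated from low-O2 light curves
#' (see [calibrate_alpha_beta()]).
#'
#' @param value alpha-beta, in (0, 1].
#' @param source `"provisional_constant"` or `"calibrated"`.
#' @return An object of class `absorptance_factor`.
#' @export
absorptance_factor <- function(value = 0.42,
                               source = c("provisional_constant", "calibrated")) {
  check_number(value, "value", len = 1)
  if (value <= 0 || value > 1) stopf("alpha-beta must be in (0, 1]")
  structure(list(alpha_beta = value, source = match.arg(source)),
            class = "absorptance_factor")
}

#' @export
print.absorptance_factor <- function(x, ...) {
  cat(sprintf("<absorptance_factor> alpha-beta = %.4g (%s)\n",
              x$alpha_beta, x$source))
  invisible(x)
}

# accept either an absorptance_factor or a bare number
as_alpha_beta <- function(ab) {
  if (inherits(ab, "absorptance_factor")) return(ab$alpha_beta)
  check_number(ab, "alpha_beta", len = 1)
  if (ab <= 0 || ab > 1) stopf("alpha-beta must be in (0, 1]")
  ab
}

#' Effective quantum yield of PSII in the light
#'
#' `phiPSII = (Fm' - Fs) / Fm'` from steady-state (`Fs`) and light-adapted
#' maximal (`Fm'`) fluorescence. `Fs > Fm'` signals swapped channels and is
#' an error, not a clipped value.
#'
#' @param fs steady-state fluorescence in the light (> 0). Vectorised.
#' @param fm_prime light-adapted maximal fluorescence (> 0). Vectorised.
#' @return Dimensionless yield in `[0, 1)`.
#' @examples
#' phi_psii(300, 600) # 0.5
#' @export
phi_psii <- function(fs, fm_prime) {
  check_number(fs, "fs", positive = TRUE)
  check_number(fm_prime, "fm_prime", positive = TRUE)
  if (any(fs > fm_prime))
    stopf("Fs > Fm': fluorescence ordering violated (swapped channels?)")
  (fm_prime - fs) / fm_prime
}

#' Non-photochemical quenching
#'
#' `NPQ = (Fm - Fm') / Fm'` from dark-adapted maximal (`Fm`) and
#' light-adapted maximal (`Fm'`) fluorescence; a proxy for regulated heat
#' dissipation of excess excitation energy.
#'
#' @param fm dark-adapted maximal fluorescence (> 0). Vectorised.
#' @param fm_prime light-adapted maximal fluorescence (> 0). Vectorised.
#' @return Dimensionless NPQ, >= 0.
#' @examples
#' npq(1000, 500) # 1
#' @export
npq <- function(fm, fm_prime) {
  check_number(fm, "fm", positive = TRUE)
  check_number(fm_prime, "fm_prime", positive = TRUE)
  if (any(fm < fm_prime))
    stopf("Fm < Fm': fluorescence ordering violated")
  (fm - fm_prime) / fm_prime
}

#' Maximum dark-adapted quantum yield of PSII
#'
#' `Fv/Fm = (Fm - F0) / Fm`; the standard health / photoinhibition
#' indicator (healthy values typically 0.6-0.8).
#'
#' @param f0 dark basal fluorescence (> 0). Vectorised.
#' @param fm dark maximal fluorescence (> 0). Vectorised.
#' @return Dimensionless ratio in `[0, 1)`.
#' @examples
#' fv_over_fm(200, 1000) # 0.8
#' @export
fv_over_fm <- function(f0, fm) {
  check_number(f0, "f0", positive = TRUE)
  check_number(fm, "fm", positive = TRUE)
  if (any(f0 > fm)) stopf("F0 > Fm: fluorescence ordering violated")
  (fm - f0) / fm
}

#' Electron transport rate through PSII
#'
#' `ETR = phiPSII * PPFD * alpha-beta`: fluorescence yield times incident
#' photon flux times the absorptance-partitioning factor.
#'
#' @param phi effective PSII yield in `[0, 1)`. Vectorised.
#' @param ppfd incident photon flux density, umol photons m-2 s-1 (>= 0).
#' @param alpha_beta an [absorptance_factor()] or bare number in (0, 1];
#'   default is the provisional constant 0.42.
#' @return ETR in umol electrons m-2 s-1.
#' @examples
#' electron_transport_rate(0.5, 800) # 168
#' @export
electron_transport_rate <- function(phi, ppfd, alpha_beta = absorptance_factor()) {
  check_number(phi, "phi")
  if (any(phi < 0 | phi >= 1)) stopf("phi must be in [0, 1)")
  check_number(ppfd, "ppfd", nonneg = TRUE)
  phi * ppfd * as_alpha_beta(alpha_beta)
}
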