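# CODATA 2018 exact values; R in kcal/(mol K) so barriers come out in kcal/mol
.kB <- 1.380649e-23      # J/K
.h  <- 6.62607015e-34    # J s
.R_kcal <- 1.98720425864083e-3  # kcal/(mol K)

#' Convert a rate constant to an activation free energy (Eyring equation)
#'
#' Transition-state theory relates a (pseudo-)first-order rate constant to the
#' activation free energy via \eqn{k = (k_B T / h)\,\exp(-\Delta G^\ddagger / RT)},
#' assuming a transmission coefficient of one. Second-order rate constants
#' should be converted to pseudo-first-order at the 1 M standard state before
#' calling this function.
#'
#' @param rate_constant Rate constant in s^-1, > 0. Vectorised.
#' @param temperature Absolute temperature in K, > 0. Vectorised (recycled).
#' @return Activation free energy \eqn{\Delta G^\ddagger} in kcal/mol.
#' @seealso [inverse_eyring()] for the exact inverse.
#' @examples
#' eyring_barrier(1e-4, 298.15)   # ~22.91 kcal/mol
#' @export
eyring_barrier <- function(rate_constant, temperature) {
  if (any(!is.finite(rate_constant)) || any(rate_constant <= 0))
    stop("rate_constant must be finite and > 0")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be finite and > 0")
  .R_kcal * temperature * log(.kB * temperature / (.h * rate_constant))
}

#' Convert an activation free energy to a rate constant
#'
#' Exact inverse of [eyring_barrier()]: \eqn{k = (k_B T/h) e^{-\Delta G^\ddagger/RT}}.
#'
#' @param dG Activation free energy in kcal/mol. Vectorised.
#' @param temperature Absolute temperature in K, > 0.
#' @return Rate constant in s^-1.
#' @export
inverse_eyring <- function(dG, temperature) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("temperature must be finite and > 0")
  if (any(!is.finite(dG))) stop("dG must be finite")
  (.kB * temperature / .h) * exp(-dG / (.R_kcal * temperature))
}
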