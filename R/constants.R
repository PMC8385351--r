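#' Physical constants and potential scaling
#'
#' Chemical potentials are handled throughout in Faraday-scaled form: the
#' molar Gibbs energy divided by Faraday's constant, expressed in millivolts.
#' This puts metabolic thermodynamics on the same scale as redox potentials
#' and makes the thermal potential \eqn{\phi_N = RT/F} (about 26.7 mV at
#' 310 K) the natural unit of driving force.
#'
#' @name potential-scaling
NULL

.GAS_CONSTANT <- 8.314      # J / (mol K)
.FARADAY <- 96485           # C / mol

#' Thermal potential RT/F
#'
#' @param temperature Absolute temperature in kelvin (default 310 K).
#' @return Thermal potential \eqn{\phi_N = RT/F} in millivolts.
#' @examples
#' thermalPotential()        # ~26.7 mV
#' thermalPotential(298.15)  # ~25.7 mV
#' @export
thermalPotential <- function(temperature = 310) {
    stopifnot(is.numeric(temperature), all(temperature > 0))
    1000 * .GAS_CONSTANT * temperature / .FARADAY
}

#' Convert molar Gibbs energy to Faraday-scaled potential
#'
#' \eqn{\phi = 10^6 \mu / F} converts a chemical potential \eqn{\mu} in
#' kJ/mol to a potential in mV; `faradayUnscale()` is the exact inverse.
#'
#' @param mu Chemical potential(s) in kJ/mol.
#' @param phi Faraday-scaled potential(s) in mV.
#' @return `faradayScale()`: potential in mV; `faradayUnscale()`: kJ/mol.
#' @examples
#' faradayScale(96.485)  # 1000 mV
#' faradayUnscale(faradayScale(-31.8))
#' @export
faradayScale <- function(mu) {
    1e6 * mu / .FARADAY
}

#' @rdname faradayScale
#' @export
faradayUnscale <- function(phi) {
    phi * .FARADAY / 1e6
}
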