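# Physical constants, CODATA 2018. Field positions depend on these to
# < 0.01 mT, so they are pinned rather than taken from any runtime source.

#' Physical constants used throughout the package (CODATA 2018)
#'
#' @format A named list with elements
#' \describe{
#'   \item{h}{Planck constant, J s}
#'   \item{mu_B}{Bohr magneton, J/T}
#'   \item{g_e}{free-electron g-value (dimensionless)}
#'   \item{mhz_per_mt}{\eqn{\mu_B/h} in MHz per mT, the electron
#'     gyromagnetic conversion at g = 1}
#' }
#' @export
epr_constants <- list(
  h = 6.62607015e-34,
  mu_B = 9.2740100783e-24,
  g_e = 2.00231930436,
  mhz_per_mt = 9.2740100783e-24 / 6.62607015e-34 * 1e-9
)

# field (mT) of an electron Zeeman resonance: B = h nu / (g mu_B)
field_from_freq <- function(freq_GHz, g) {
  1e3 * freq_GHz / (g * epr_constants$mhz_per_mt)
}

# FWHM (MHz) -> field FWHM (mT) at effective g
mhz_to_mt <- function(width_MHz, g_eff) {
  width_MHz / (g_eff * epr_constants$mhz_per_mt)
}

FWHM_TO_SIGMA <- 1 / (2 * sqrt(2 * log(2)))
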