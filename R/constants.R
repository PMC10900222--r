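#' Physical constants
#'
#' Boltzmann constant in kcal/(mol K).  At the default simulation
#' temperature of 300 K, \code{kB * 300 = 0.59616} kcal/mol.
#'
#' @format A single numeric value.
#' @export
kB <- 0.0019872041

#' Thermal energy k_B T
#'
#' @param temperature temperature in K.
#' @return k_B T in kcal/mol.
#' @export
kBT <- function(temperature = 300) kB * temperature

#' Wrap angles into the working interval [-90, 270) degrees
#'
#' The interval keeps both wells (cis near 0, trans near 180) and the studied
#' barrier (near 90) in the interior of the coordinate; the periodic image of
#' the second barrier sits at the interval edges (-90/270).
#'
#' @param x angles in degrees.
#' @return wrapped angles in [-90, 270).
#' @export
wrap_angle <- function(x) {
  ((x + 90) %% 360) - 90
}

#' Minimal periodic angle difference
#'
#' @param x angle differences in degrees.
#' @return equivalent differences in [-180, 180).
#' @export
angle_diff <- function(x) {
  ((x + 180) %% 360) - 180
}
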