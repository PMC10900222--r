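#' Boltzmann-inversion free-energy profile by quadrature
#'
#' Reference profile computed directly from the potential:
#' \code{A_i = -kB T ln} of the within-bin integral of \code{exp(-beta V)}
#' (trapezoid quadrature), anchored at min = 0.  Independent of any
#' sampling or histogram reweighting; used as the analytic oracle for the
#' WHAM path.
#'
#' @param pot a [torsion_potential()].
#' @param bins a [wham_bins()] spec.
#' @param temperature K.
#' @param n_sub quadrature points per bin.
#' @return a [free_energy_profile()].
#' @export
boltzmann_profile <- function(pot, bins = wham_bins(), temperature = 300,
                              n_sub = 20) {
  beta <- 1 / kBT(temperature)
  A <- sapply(seq_len(bins$n), function(i) {
    x <- seq(bins$breaks[i], bins$breaks[i + 1], length.out = n_sub)
    -kBT(temperature) * log(pracma::trapz(x, exp(-beta * potential_energy(pot, x))))
  })
  free_energy_profile(bins$centers, A - min(A), A_err = rep(0, bins$n),
                      alpha = pot$alpha, temperature = temperature, bins = bins)
}

#' Mean first-passage time by double-integral quadrature
#'
#' MFPT of one-dimensional overdamped diffusion on the potential, started
#' at \code{start}, with absorbing boundaries at both \code{lower} and
#' \code{upper} (matching first-crossing detection on the wrapped
#' coordinate, which counts escape through either barrier).  With
#' \code{reflect_upper = TRUE} the upper boundary is reflecting instead.
#'
#' @param pot a [torsion_potential()].
#' @param D diffusion coefficient, deg^2/s.
#' @param start starting angle, degrees.
#' @param lower,upper boundary angles, degrees.
#' @param temperature K.
#' @param reflect_upper make the upper boundary reflecting.
#' @param n_grid quadrature grid size.
#' @return MFPT in seconds.
#' @export
mfpt_quadrature <- function(pot, D, start = 180, lower = 90, upper = 270,
                            temperature = 300, reflect_upper = FALSE,
                            n_grid = 4001) {
  stopifnot(lower < start, start < upper)
  beta <- 1 / kBT(temperature)
  x <- seq(lower, upper, length.out = n_grid)
  V <- potential_energy(pot, x)
  V <- V - min(V)
  phi <- exp(-beta * V)            # e^{-beta V}
  Phi <- as.vector(pracma::cumtrapz(x, phi))  # integral of phi from 'lower'
  inv_phi <- exp(beta * V)
  # phi T' = C - Phi/D  ->  T(x) = int (C - Phi/D)/phi
  if (reflect_upper) {
    C <- Phi[n_grid] / D
  } else {
    num <- pracma::trapz(x, inv_phi * Phi) / D
    den <- pracma::trapz(x, inv_phi)
    C <- num / den
  }
  integrand <- (C - Phi / D) * inv_phi
  Tx <- as.vector(pracma::cumtrapz(x, integrand))
  as.numeric(stats::approx(x, Tx, xout = start)$y)
}
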