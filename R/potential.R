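#' Periodic dihedral potential with barrier scaling
#'
#' Builds a torsional potential of the standard cosine-series form
#' \deqn{V(\phi) = \alpha \sum_n (V_n/2)\,[1 + \cos(n\phi - \gamma_n)] + V_{bg}(\phi)}
#' where the dihedral terms are scaled by a factor \code{alpha} in (0, 1]
#' (reduced-barrier potentials used to make barrier crossing tractable) and
#' an optional unscaled background series represents the smooth periodic
#' contribution of the environment (e.g. distinct well depths for a torsion
#' embedded in a protein).
#'
#' With a single term \code{(n = 2, V = 28, gamma = 180)} the minima sit at
#' 0 and 180 degrees and the maxima at +-90 degrees with height \code{V}.
#'
#' @param terms matrix-like with columns \code{n} (periodicity),
#'   \code{V} (amplitude, kcal/mol), \code{gamma} (phase, degrees); a single
#'   term may be given as \code{c(n, V, gamma)}.
#' @param alpha dimensionless scaling of the dihedral terms, in (0, 1].
#' @param background optional background series in the same format; never
#'   scaled by \code{alpha}.
#' @return an object of class \code{"torsion_potential"}.
#' @examples
#' pot <- torsion_potential(c(2, 28, 180))
#' potential_energy(pot, c(0, 90, 180))
#' @export
torsion_potential <- function(terms, alpha = 1, background = NULL) {
  terms <- .as_term_matrix(terms)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1)
    stop("'alpha' must be a single value in (0, 1]")
  if (any(terms[, "n"] <= 0) || any(terms[, "n"] != round(terms[, "n"])))
    stop("periodicities must be positive integers")
  bg <- if (is.null(background)) .as_term_matrix(NULL) else .as_term_matrix(background)
  structure(list(terms = terms, alpha = alpha, background = bg),
            class = "torsion_potential")
}

.as_term_matrix <- function(x) {
  if (is.null(x))
    return(matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("n", "V", "gamma"))))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) x <- matrix(x, ncol = 3, byrow = TRUE)
  if (ncol(x) != 3) stop("terms must have columns n, V, gamma")
  colnames(x) <- c("n", "V", "gamma")
  x
}

#' @export
print.torsion_potential <- function(x, ...) {
  cat("Torsion potential: alpha =", x$alpha, "\n")
  cat("  dihedral terms (n, V kcal/mol, gamma deg):\n")
  print(x$terms)
  if (nrow(x$background)) {
    cat("  background terms:\n")
    print(x$background)
  }
  invisible(x)
}

.series_energy <- function(terms, phi) {
  e <- numeric(length(phi))
  for (i in seq_len(nrow(terms))) {
    e <- e + 0.5 * terms[i, "V"] *
      (1 + cos((terms[i, "n"] * phi - terms[i, "gamma"]) * pi / 180))
  }
  e
}

.series_gradient <- function(terms, phi) {
  g <- numeric(length(phi))
  for (i in seq_len(nrow(terms))) {
    g <- g - 0.5 * terms[i, "V"] * terms[i, "n"] *
      sin((terms[i, "n"] * phi - terms[i, "gamma"]) * pi / 180) * pi / 180
  }
  g
}

#' Potential energy at given torsion angles
#'
#' @param pot a [torsion_potential()].
#' @param phi angles in degrees (vectorized).
#' @return energies in kcal/mol; 360-periodic in \code{phi}.
#' @export
potential_energy <- function(pot, phi) {
  stopifnot(inherits(pot, "torsion_potential"))
  unname(pot$alpha * .series_energy(pot$terms, phi) + .series_energy(pot$background, phi))
}

#' Potential gradient dV/dphi
#'
#' @inheritParams potential_energy
#' @return gradient in kcal mol^-1 deg^-1.
#' @export
potential_gradient <- function(pot, phi) {
  stopifnot(inherits(pot, "torsion_potential"))
  unname(pot$alpha * .series_gradient(pot$terms, phi) + .series_gradient(pot$background, phi))
}
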