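#' Overdamped Kramers rate from barrier statistics
#'
#' \deqn{k = \frac{\omega_0\,\omega_b\,\beta D}{2\pi} e^{-\beta \Delta G^\ddagger}}
#' where \eqn{\omega_0 = \sqrt{|curv_{well}|}} and
#' \eqn{\omega_b = \sqrt{|curv_{barrier}|}} are square-rooted free-energy
#' curvatures (units (kcal/mol)^{1/2} deg^-1, the only reading that makes
#' the prefactor an inverse time with D in deg^2/s) and
#' \eqn{\beta = 1/k_B T}.
#'
#' @param dG activation free energy, kcal/mol.
#' @param curv_well curvature of the reactant well, kcal mol^-1 deg^-2 (> 0).
#' @param curv_barrier curvature at the barrier top (< 0; the magnitude is
#'   used).
#' @param D diffusion coefficient along the coordinate, deg^2/s.
#' @param temperature K.
#' @return rate constant, s^-1.
#' @export
rate_from_kramers <- function(dG, curv_well, curv_barrier, D, temperature = 300) {
  if (curv_well <= 0) stop("'curv_well' must be positive")
  if (curv_barrier == 0) stop("'curv_barrier' must be nonzero")
  if (D <= 0) stop("'D' must be positive")
  beta <- 1 / kBT(temperature)
  sqrt(curv_well) * sqrt(abs(curv_barrier)) * beta * D / (2 * pi) *
    exp(-beta * dG)
}

#' Assemble a per-alpha input point for the Kramers regression
#'
#' @param alpha barrier scaling of the measurement.
#' @param dG activation free energy [measurement()] (kcal/mol).
#' @param k measured rate [measurement()] (s^-1).
#' @param curv_well,curv_barrier stationary-point curvature
#'   [measurement()]s (kcal mol^-1 deg^-2); the well positive, the barrier
#'   negative.
#' @return one-row data.frame of class \code{"kramers_point"}.
#' @export
kramers_point <- function(alpha, dG, k, curv_well, curv_barrier) {
  stopifnot(k$value > 0, curv_well$value > 0, curv_barrier$value < 0)
  structure(data.frame(alpha = alpha,
                       dG = dG$value, dG_err = dG$sd,
                       k = k$value, k_err = k$sd,
                       curv_well = curv_well$value, curv_well_err = curv_well$sd,
                       curv_barrier = curv_barrier$value,
                       curv_barrier_err = curv_barrier$sd),
            class = c("kramers_point", "data.frame"))
}

# y = ln(k / (w0 wb)) and its first-order error
.kramers_y <- function(points) {
  w0 <- sqrt(points$curv_well); wb <- sqrt(abs(points$curv_barrier))
  y <- log(points$k / (w0 * wb))
  s2 <- (points$k_err / points$k)^2 +
    0.25 * (points$curv_well_err / points$curv_well)^2 +
    0.25 * (points$curv_barrier_err / points$curv_barrier)^2
  list(y = y, y_err = sqrt(s2))
}

#' Fixed-slope Kramers regression for the effective diffusion coefficient
#'
#' Linear model \eqn{y_i = c - \beta\,\Delta G^\ddagger_i} for
#' \eqn{y_i = \ln(k_i/\omega_{0,i}\omega_{b,i})} with the slope fixed at
#' \eqn{-1/k_B T}; the intercept is the variance-weighted mean of
#' \eqn{y_i + \beta \Delta G^\ddagger_i} (weights from first-order
#' propagated y errors, unweighted fallback when errors are absent), and
#' \eqn{D_{eff} = 2\pi k_B T e^{c}}.
#'
#' @param points a data.frame of [kramers_point()] rows (>= 1).
#' @param temperature K.
#' @return object of class \code{"kramers_fit"}: \code{D_eff} and
#'   \code{intercept} as [measurement()]s, the per-point \code{y} values
#'   and residuals, and \code{temperature}.
#' @export
kramers_regression <- function(points, temperature = 300) {
  stopifnot(nrow(points) >= 1)
  beta <- 1 / kBT(temperature)
  yy <- .kramers_y(points)
  ci <- yy$y + beta * points$dG
  s2 <- yy$y_err^2 + (beta * points$dG_err)^2
  if (all(is.finite(s2)) && all(s2 > 0)) {
    w <- 1 / s2
    c_hat <- sum(w * ci) / sum(w)
    c_err <- sqrt(1 / sum(w))
    weighted <- TRUE
  } else {
    c_hat <- mean(ci)
    c_err <- if (nrow(points) > 1) sd(ci) / sqrt(nrow(points)) else 0
    weighted <- FALSE
  }
  D_eff <- 2 * pi * kBT(temperature) * exp(c_hat)
  structure(list(D_eff = measurement(D_eff, D_eff * c_err),
                 intercept = measurement(c_hat, c_err),
                 y = yy$y, y_err = yy$y_err,
                 residuals = yy$y - (c_hat - beta * points$dG),
                 points = points, weighted = weighted,
                 temperature = temperature),
            class = "kramers_fit")
}

#' @export
print.kramers_fit <- function(x, ...) {
  cat("Kramers fixed-slope fit (", nrow(x$points), " point(s), T =",
      x$temperature, "K)\n  D_eff =", format(x$D_eff$value, digits = 4),
      "+-", format(x$D_eff$sd, digits = 2), "deg^2/s\n")
  invisible(x)
}

#' Extrapolate the rate to a target barrier along the fitted line
#'
#' Evaluates the overdamped Kramers rate at the target activation free
#' energy and curvatures using the fitted effective diffusion coefficient;
#' the error combines the intercept and target uncertainties by first-order
#' propagation.
#'
#' @param fit a [kramers_regression()] result.
#' @param dG_target target activation free energy [measurement()]
#'   (kcal/mol), e.g. at the unmodified potential.
#' @param curv_well,curv_barrier target curvatures as [measurement()]s.
#' @param temperature K (defaults to the fit temperature).
#' @return the extrapolated rate as a [measurement()] (s^-1).
#' @export
extrapolate_rate <- function(fit, dG_target, curv_well, curv_barrier,
                             temperature = fit$temperature) {
  beta <- 1 / kBT(temperature)
  k <- rate_from_kramers(dG_target$value, curv_well$value, curv_barrier$value,
                         fit$D_eff$value, temperature)
  e0 <- function(s) if (is.na(s)) 0 else s
  s_lnk <- sqrt(fit$intercept$sd^2 + (beta * e0(dG_target$sd))^2 +
                0.25 * (e0(curv_well$sd) / curv_well$value)^2 +
                0.25 * (e0(curv_barrier$sd) / curv_barrier$value)^2)
  measurement(k, k * s_lnk)
}
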