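#' Superpose free-energy profiles at their alpha-insensitive anchors
#'
#' Each profile is shifted by the constant that minimizes its squared
#' difference to the first profile at the bins nearest 0 and 180 degrees
#' (the wells, where the influence of the barrier scaling is negligible);
#' the first profile is left unshifted.
#'
#' @param profiles list of [free_energy_profile()]s on a common bin grid.
#' @return the shifted profiles, with attribute \code{"shifts"}.
#' @export
superpose_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  g <- profiles[[1]]$bin_centers
  for (p in profiles)
    if (!isTRUE(all.equal(p$bin_centers, g))) stop("profiles have different bin grids")
  anchors <- c(which.min(abs(g - 0)), which.min(abs(g - 180)))
  ref <- profiles[[1]]$A[anchors]
  shifts <- sapply(profiles, function(p) {
    ok <- !is.na(ref) & !is.na(p$A[anchors])
    if (!any(ok)) stop("no sampled anchor bins shared with the first profile")
    mean(ref[ok] - p$A[anchors][ok])
  })
  out <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]; p$A <- p$A + shifts[i]; p
  })
  attr(out, "shifts") <- shifts
  out
}

#' Extrapolate reduced-barrier profiles to the unmodified potential
#'
#' First-order cumulant scheme: for each bin, the free energy measured at
#' scaling alpha obeys \eqn{A(\omega;\alpha) = A_0(\omega) - (1-\alpha) B(\omega)}
#' with \eqn{B(\omega)} the mean unmodified dihedral energy at fixed omega,
#' so a per-bin (variance-weighted) linear regression of \eqn{A(\omega;\alpha)}
#' on \eqn{1-\alpha} yields the unmodified profile \eqn{A_0(\omega)} as the
#' intercept and \eqn{-B(\omega)} as the slope.  Higher-order cumulants are
#' ignored.  Profiles should be superposed first (see
#' [superpose_profiles()]); weights are per-bin inverse variances from the
#' bootstrap errors, falling back to an unweighted fit when a bin has no
#' usable errors.
#'
#' @param profiles list of [free_energy_profile()]s (superposed, common grid).
#' @param alphas scaling factors, one per profile (>= 2 distinct values);
#'   taken from the profiles when omitted.
#' @return list of class \code{"extrapolation_result"}: \code{A0} a
#'   [free_energy_profile()] with intercept errors (anchored at min 0),
#'   \code{B} per-bin slopes (kcal/mol), and a per-bin \code{diagnostics}
#'   data.frame (\code{r_squared}, \code{weighted}, \code{n_alpha}).
#' @export
extrapolate_profile <- function(profiles, alphas = NULL) {
  if (is.null(alphas)) alphas <- sapply(profiles, function(p) p$alpha)
  stopifnot(length(profiles) == length(alphas))
  if (length(unique(alphas)) < 2)
    stop("at least 2 distinct alpha values are required")
  g <- profiles[[1]]$bin_centers
  nb <- length(g)
  x <- 1 - alphas
  Amat <- sapply(profiles, function(p) p$A)
  Emat <- sapply(profiles, function(p) p$A_err)
  A0 <- B <- A0_err <- r2 <- rep(NA_real_, nb)
  weighted <- rep(NA, nb); n_alpha <- integer(nb)
  for (i in seq_len(nb)) {
    y <- Amat[i, ]; e <- Emat[i, ]
    ok <- !is.na(y)
    n_alpha[i] <- sum(ok)
    if (sum(ok) < 2 || length(unique(x[ok])) < 2) next  # flagged missing
    use_w <- all(!is.na(e[ok]) & e[ok] > 0)
    X <- cbind(1, x[ok])
    if (use_w) {
      W <- diag(1 / e[ok]^2, nrow = sum(ok))
      XtWX <- solve(t(X) %*% W %*% X)
      b <- XtWX %*% t(X) %*% W %*% y[ok]
      A0_err[i] <- sqrt(XtWX[1, 1])  # variance-known intercept error
    } else {
      fit <- lm(y[ok] ~ x[ok])
      b <- matrix(coef(fit))
      A0_err[i] <- if (sum(ok) > 2) suppressWarnings(sqrt(diag(vcov(fit)))[1]) else 0
    }
    A0[i] <- b[1]; B[i] <- -b[2]
    fitted <- X %*% b
    ss_res <- sum((y[ok] - fitted)^2); ss_tot <- sum((y[ok] - mean(y[ok]))^2)
    r2[i] <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
    weighted[i] <- use_w
  }
  if (any(weighted %in% FALSE))
    message("unweighted regression used for ", sum(weighted %in% FALSE),
            " bin(s) lacking usable errors")
  shift <- min(A0, na.rm = TRUE)
  counts <- rowSums(sapply(profiles, function(p) {
    cn <- p$counts
    if (is.null(cn) || all(is.na(cn))) rep(0L, nb) else cn
  }))
  structure(list(
    A0 = free_energy_profile(g, A0 - shift, A0_err, counts = counts,
                             alpha = 1, temperature = profiles[[1]]$temperature,
                             bins = profiles[[1]]$bins),
    B = B,
    alphas = alphas,
    diagnostics = data.frame(bin_center = g, r_squared = r2,
                             weighted = weighted, n_alpha = n_alpha)),
    class = "extrapolation_result")
}
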