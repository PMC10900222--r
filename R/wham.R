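#' Uniform bin specification for free-energy profiles
#'
#' Default: 80 uniform bins spanning -31.5 to 208.5 degrees, half-open
#' \code{[left, right)} assignment.
#'
#' @param n number of bins.
#' @param lo,hi range limits, degrees.
#' @return list with \code{breaks}, \code{centers}, \code{width}.
#' @export
wham_bins <- function(n = 80, lo = -31.5, hi = 208.5) {
  stopifnot(n >= 1, hi > lo)
  breaks <- seq(lo, hi, length.out = n + 1)
  list(n = n, lo = lo, hi = hi, breaks = breaks,
       centers = (breaks[-1] + breaks[-(n + 1)]) / 2,
       width = (hi - lo) / n)
}

.bin_counts <- function(omega, bins) {
  idx <- floor((omega - bins$lo) / bins$width) + 1
  idx <- idx[idx >= 1 & idx <= bins$n]
  tabulate(idx, nbins = bins$n)
}

#' Estimate the decorrelation time of a torsion time series
#'
#' Twice the first lag at which the normalized autocorrelation of omega
#' falls below 1/e (the empirical two-fold-decay rule used to decorrelate
#' umbrella-sampling data).
#'
#' @param series a \code{"trajectory_series"}.
#' @return decorrelation time in seconds.
#' @export
estimate_decorrelation <- function(series) {
  x <- series$omega
  if (length(x) < 100) stop("series too short (< 100 samples)")
  if (sd(x) == 0) stop("constant series: autocorrelation undefined")
  a <- acf(x, lag.max = length(x) - 1, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lag <- which(a < exp(-1))[1] - 1  # acf[1] is lag 0
  if (is.na(lag)) stop("autocorrelation never decays below 1/e")
  2 * lag * series$metadata$dt
}

#' Free-energy profile container
#'
#' @param bin_centers bin centers, degrees (strictly increasing, uniform).
#' @param A free energy per bin, kcal/mol, anchored at min = 0; NA flags
#'   unsampled bins.
#' @param A_err per-bin bootstrap errors (kcal/mol) or NA.
#' @param counts per-bin sample counts.
#' @param alpha scaling of the generating potential.
#' @param temperature K.
#' @param bins the [wham_bins()] spec.
#' @return object of class \code{"free_energy_profile"}.
#' @export
free_energy_profile <- function(bin_centers, A, A_err = rep(NA_real_, length(A)),
                                counts = rep(NA_integer_, length(A)),
                                alpha = NA_real_, temperature = 300,
                                bins = NULL) {
  stopifnot(length(A) == length(bin_centers), length(A_err) == length(A))
  if (any(diff(bin_centers) <= 0)) stop("bin centers must be strictly increasing")
  structure(list(bin_centers = bin_centers, A = A, A_err = A_err,
                 counts = counts, alpha = alpha, temperature = temperature,
                 bins = bins),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat("Free-energy profile:", length(x$A), "bins,",
      sum(!is.na(x$A)), "sampled; alpha =", x$alpha, "\n")
  invisible(x)
}

# window bias energies at bin centers: 0.5 k (minimal image difference)^2
.bias_matrix <- function(windows, bins) {
  sapply(windows, function(w) {
    r <- w$restraint
    if (is.null(r) || r$force_constant == 0) return(rep(0, bins$n))
    0.5 * r$force_constant * angle_diff(bins$centers - r$reference_omega)^2
  })
}

.check_connectivity <- function(counts_mat) {
  nw <- ncol(counts_mat)
  if (nw == 1) return(invisible(TRUE))
  occupied <- counts_mat > 0
  seen <- rep(FALSE, nw); seen[1] <- TRUE; frontier <- 1
  while (length(frontier)) {
    nxt <- integer(0)
    for (j in frontier) {
      link <- which(!seen & colSums(occupied & occupied[, j]) > 0)
      seen[link] <- TRUE
      nxt <- c(nxt, link)
    }
    frontier <- nxt
  }
  if (!all(seen))
    stop("disconnected windows: no histogram overlap joining windows ",
         paste(which(!seen), collapse = ", "), " to window 1")
  invisible(TRUE)
}

#' Weighted histogram analysis (WHAM) of umbrella windows
#'
#' Standard self-consistent WHAM iteration over the window free-energy
#' shifts; iterates until the largest change of any shift is below
#' \code{tolerance} (kcal/mol).  The unbiased probability is converted to
#' \code{A = -kB T ln P}, anchored so that the minimum over sampled bins
#' is zero.
#'
#' @param windows list of \code{list(restraint, series)} as produced by
#'   [generate_umbrella_set()]; a window with \code{restraint = NULL} or a
#'   zero force constant is unbiased.
#' @param bins a [wham_bins()] spec.
#' @param temperature K.
#' @param tolerance convergence tolerance on the shifts, kcal/mol.
#' @param max_iter iteration cap.
#' @return a [free_energy_profile()] (errors NA; see
#'   [bootstrap_profile_errors()]).
#' @export
wham_solve <- function(windows, bins = wham_bins(), temperature = 300,
                       tolerance = 1e-6, max_iter = 1e5) {
  stopifnot(length(windows) >= 1)
  counts <- sapply(windows, function(w) .bin_counts(w$series$omega, bins))
  counts <- matrix(counts, nrow = bins$n)
  .check_connectivity(counts)
  H <- rowSums(counts)            # per-bin totals
  N <- colSums(counts)            # per-window totals (in range)
  if (any(N == 0)) stop("window(s) with no samples in the binned range: ",
                        paste(which(N == 0), collapse = ", "))
  beta <- 1 / kBT(temperature)
  cmat <- exp(-beta * .bias_matrix(windows, bins))  # n_bins x n_windows
  a <- rep(0, length(windows))    # shifts, kcal/mol
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- as.vector(cmat %*% (N * exp(beta * a)))
    p <- ifelse(H > 0, H / denom, 0)
    a_new <- -kBT(temperature) * log(as.vector(t(cmat) %*% p))
    a_new <- a_new - a_new[1]
    delta <- max(abs(a_new - a))
    a <- a_new
    if (delta < tolerance) break
    if (iter >= max_iter)
      stop("WHAM failed to converge in ", max_iter,
           " iterations (last change ", signif(delta, 3), " kcal/mol)")
  }
  A <- ifelse(H > 0, -kBT(temperature) * log(p), NA_real_)
  A <- A - min(A, na.rm = TRUE)
  alpha <- windows[[1]]$series$metadata$alpha
  pr <- free_energy_profile(bins$centers, A, counts = H, alpha = alpha,
                            temperature = temperature, bins = bins)
  pr$iterations <- iter
  pr
}

# decorrelated-index resampling of one series
.resample_series <- function(series, stride) {
  n <- length(series$omega)
  phase <- sample.int(stride, 1)
  idx <- seq(phase, n, by = stride)
  pick <- sample(idx, length(idx), replace = TRUE)
  out <- series
  out$omega <- series$omega[pick]
  out$times <- series$times[seq_along(pick)]
  out
}

#' Monte Carlo bootstrap errors for a WHAM profile
#'
#' Each trial resamples, per window, the decorrelated points (every
#' \code{ceiling(decorrelation/dt)}-th sample at a random phase, resampled
#' with replacement) and re-solves WHAM; the per-bin error is the standard
#' deviation across trials.
#'
#' @inheritParams wham_solve
#' @param n_trials number of bootstrap trials (default 10).
#' @param decorrelation decorrelation time, s (see
#'   [estimate_decorrelation()]).
#' @param seed RNG seed for the resampling (default 1234).
#' @return the full-data [free_energy_profile()] with \code{A_err} filled.
#' @export
bootstrap_profile_errors <- function(windows, bins = wham_bins(),
                                     temperature = 300, n_trials = 10,
                                     decorrelation, seed = 1234,
                                     tolerance = 1e-6) {
  durations <- sapply(windows, function(w) max(w$series$times) - min(w$series$times))
  if (any(decorrelation > durations))
    stop("decorrelation time exceeds the duration of window(s) ",
         paste(which(decorrelation > durations), collapse = ", "))
  full <- wham_solve(windows, bins, temperature, tolerance)
  strides <- sapply(windows, function(w)
    max(1L, as.integer(round(decorrelation / w$series$metadata$dt))))
  trials <- .with_seed(seed, {
    sapply(seq_len(n_trials), function(t) {
      wb <- lapply(seq_along(windows), function(j) {
        list(restraint = windows[[j]]$restraint,
             series = .resample_series(windows[[j]]$series, strides[j]))
      })
      wham_solve(wb, bins, temperature, tolerance)$A
    })
  })
  err <- apply(matrix(trials, nrow = bins$n), 1, sd, na.rm = TRUE)
  full$A_err <- ifelse(full$counts > 0, err, NA_real_)
  full$bootstrap <- list(n_trials = n_trials, seed = seed,
                         decorrelation = decorrelation)
  full
}

#' Locate the cis well, trans well and transition state on a profile
#'
#' Wells are the free-energy minima within the search boxes 0 +- 45 and
#' 180 +- 45 degrees; the transition state is the maximum strictly between
#' them.
#'
#' @param profile a [free_energy_profile()].
#' @param box_halfwidth half-width of the well search boxes, degrees.
#' @return list with \code{omega_cis}, \code{omega_ts}, \code{omega_trans}
#'   (degrees) and the corresponding bin indices.
#' @export
locate_states <- function(profile, box_halfwidth = 45) {
  x <- profile$bin_centers; A <- profile$A
  find_min <- function(center) {
    box <- which(abs(x - center) <= box_halfwidth & !is.na(A))
    if (length(box) < 1) stop("no sampled bins in the well box around ", center)
    box[which.min(A[box])]
  }
  i_cis <- find_min(0)
  i_trans <- find_min(180)
  between <- which(x > x[i_cis] & x < x[i_trans] & !is.na(A))
  if (length(between) < 1) stop("no sampled bins between the wells")
  i_ts <- between[which.max(A[between])]
  if (A[i_ts] <= max(A[i_cis], A[i_trans]))
    stop("monotone profile: no barrier between the wells")
  list(omega_cis = x[i_cis], omega_ts = x[i_ts], omega_trans = x[i_trans],
       idx_cis = i_cis, idx_ts = i_ts, idx_trans = i_trans)
}

# quadratic fit around a stationary point; curvature = 2 * quadratic coeff
.fit_curvature <- function(profile, center, halfwidth) {
  ok <- !is.na(profile$A) & abs(angle_diff(profile$bin_centers - center)) <= halfwidth
  if (sum(ok) < 4)
    stop("fewer than 4 sampled bins within +-", halfwidth, " deg of ", center)
  xx <- angle_diff(profile$bin_centers[ok] - center)
  fit <- lm(profile$A[ok] ~ xx + I(xx^2))
  c(value = 2 * unname(coef(fit)[3]),
    sd = 2 * unname(sqrt(diag(vcov(fit)))[3]))
}

#' Barrier heights, asymmetry, and stationary-point curvatures
#'
#' Activation free energies are differences of the profile at the assigned
#' state bins (errors combined by first-order propagation); curvatures are
#' twice the quadratic coefficient of a least-squares parabola fit to the
#' bins within \code{fit_halfwidth} of each stationary point.
#'
#' @param profile a [free_energy_profile()] (bootstrap errors used if present).
#' @param states a [locate_states()] result (computed if missing).
#' @param fit_halfwidth half-width of the parabola fit window, degrees.
#' @return list of [measurement()]s: \code{dG_tc} (trans->cis barrier),
#'   \code{dG_ct} (cis->trans), \code{dG_cis_trans} (cis minus trans),
#'   \code{curv_trans}, \code{curv_cis}, \code{curv_ts}
#'   (kcal mol^-1 deg^-2), plus the states.
#' @export
barrier_stats <- function(profile, states = locate_states(profile),
                          fit_halfwidth = 10) {
  interior <- which(profile$bin_centers > states$omega_cis &
                    profile$bin_centers < states$omega_trans)
  if (any(is.na(profile$A[interior])))
    stop("unsampled interior bins between the wells; refusing to interpolate")
  A <- profile$A; E <- profile$A_err
  e <- function(i) if (is.na(E[i])) 0 else E[i]
  m <- function(i, j) measurement(A[i] - A[j],
                                  propagate_error(c(1, -1), c(e(i), e(j))))
  ct <- .fit_curvature(profile, states$omega_trans, fit_halfwidth)
  cc <- .fit_curvature(profile, states$omega_cis, fit_halfwidth)
  cb <- .fit_curvature(profile, states$omega_ts, fit_halfwidth)
  if (cb["value"] >= 0) warning("barrier curvature is not negative")
  list(dG_tc = m(states$idx_ts, states$idx_trans),
       dG_ct = m(states$idx_ts, states$idx_cis),
       dG_cis_trans = m(states$idx_cis, states$idx_trans),
       curv_trans = measurement(ct["value"], ct["sd"]),
       curv_cis = measurement(cc["value"], cc["sd"]),
       curv_ts = measurement(cb["value"], cb["sd"]),
       states = states, fit_halfwidth = fit_halfwidth)
}

#' Cumulative-time convergence trace of the free-energy differences
#'
#' Re-solves WHAM on data truncated at each cumulative block boundary and
#' reports the evolving state free-energy differences.
#'
#' @inheritParams wham_solve
#' @param block block length, s (>= 2 blocks must fit for a trace).
#' @param threshold convergence threshold on the last-block change of any
#'   free-energy difference, kcal/mol.
#' @return data.frame with columns \code{time}, \code{dG_tc}, \code{dG_ct},
#'   \code{dG_cis_trans}; attributes \code{last_change} and
#'   \code{converged}.
#' @export
convergence_trace <- function(windows, bins = wham_bins(), temperature = 300,
                              block, threshold = 0.1, tolerance = 1e-6) {
  t_max <- min(sapply(windows, function(w) max(w$series$times)))
  bounds <- seq(block, t_max, by = block)
  if (length(bounds) < 1) stop("block longer than the shortest window")
  rows <- lapply(bounds, function(b) {
    wt <- lapply(windows, function(w) {
      keep <- w$series$times <= b
      s <- w$series; s$times <- s$times[keep]; s$omega <- s$omega[keep]
      list(restraint = w$restraint, series = s)
    })
    pr <- wham_solve(wt, bins, temperature, tolerance)
    bs <- locate_states(pr)
    data.frame(time = b,
               dG_tc = pr$A[bs$idx_ts] - pr$A[bs$idx_trans],
               dG_ct = pr$A[bs$idx_ts] - pr$A[bs$idx_cis],
               dG_cis_trans = pr$A[bs$idx_cis] - pr$A[bs$idx_trans])
  })
  out <- do.call(rbind, rows)
  if (nrow(out) >= 2) {
    last <- abs(unlist(out[nrow(out), -1] - out[nrow(out) - 1, -1]))
    attr(out, "last_change") <- max(last)
    attr(out, "converged") <- max(last) < threshold
  } else {
    attr(out, "last_change") <- NA_real_
    attr(out, "converged") <- NA
  }
  out
}
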