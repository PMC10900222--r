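#' Detect the first barrier crossing in a trajectory
#'
#' A trans-to-cis event is the first sample with omega below the
#' transition-state angle; cis-to-trans the first sample above it.  A series
#' with no crossing is censored at its final time.  Events are resolved at
#' sample resolution (no interpolation between frames).
#'
#' @param series a \code{"trajectory_series"} (wrapped to [-90, 270)).
#' @param omega_ts transition-state angle, degrees (the peak of the
#'   free-energy curve between the wells; see [locate_states()]).
#' @param direction \code{"trans_to_cis"} or \code{"cis_to_trans"}.
#' @param replica_id identifier carried into the record.
#' @return one-row data.frame: \code{replica_id}, \code{time} (s),
#'   \code{status} ("event" or "censored").
#' @export
detect_transition <- function(series, omega_ts,
                              direction = c("trans_to_cis", "cis_to_trans"),
                              replica_id = 1L) {
  direction <- match.arg(direction)
  w <- series$omega
  crossed <- if (direction == "trans_to_cis") w < omega_ts else w > omega_ts
  if (crossed[1])
    stop("series starts on the product side of omega_ts = ", omega_ts)
  i <- which(crossed)[1]
  if (is.na(i))
    data.frame(replica_id = replica_id, time = series$times[length(w)],
               status = "censored")
  else
    data.frame(replica_id = replica_id, time = series$times[i],
               status = "event")
}

#' Build the event table for a set of escape replicas
#'
#' @param replicas list of \code{"trajectory_series"} (see
#'   [generate_escape_replicas()]).
#' @inheritParams detect_transition
#' @return data.frame of event records, one row per replica.
#' @export
event_records <- function(replicas, omega_ts,
                          direction = c("trans_to_cis", "cis_to_trans")) {
  direction <- match.arg(direction)
  do.call(rbind, lapply(seq_along(replicas), function(i)
    detect_transition(replicas[[i]], omega_ts, direction, replica_id = i)))
}

#' Kaplan-Meier survival curve with exponential Greenwood intervals
#'
#' Product-limit estimate of the survival probability of the reactant state
#' from event / right-censored first-passage records, with the 95%
#' exponential Greenwood (log-minus-log) confidence interval, evaluated on a
#' uniform time grid.  Estimation is delegated to
#' \code{survival::survfit(..., conf.type = "log-log")}.
#'
#' @param records data.frame with columns \code{time} and \code{status}
#'   ("event"/"censored"), as from [event_records()].
#' @param grid either a vector of evaluation times (s) or a single grid
#'   spacing; default spacing spans 0 to the latest event time in 100 steps.
#' @return object of class \code{"survival_curve"}: data.frame columns
#'   \code{time}, \code{S}, \code{ci_low}, \code{ci_high}; attributes
#'   \code{n}, \code{n_events}.
#' @export
km_survival <- function(records, grid = NULL) {
  stopifnot(nrow(records) >= 1)
  if (all(records$status == "censored" & records$time <= 0))
    stop("all records censored at time 0")
  ev <- as.integer(records$status == "event")
  fit <- survival::survfit(survival::Surv(records$time, ev) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  t_last <- if (any(ev == 1)) max(records$time[ev == 1]) else max(records$time)
  if (is.null(grid)) grid <- seq(0, t_last, length.out = 101)
  else if (length(grid) == 1) grid <- seq(0, t_last + grid, by = grid)
  sm <- summary(fit, times = grid, extend = TRUE)
  S <- sm$surv
  lo <- ifelse(is.na(sm$lower), ifelse(S >= 1, 1, 0), sm$lower)
  hi <- ifelse(is.na(sm$upper), ifelse(S <= 0, 0, 1), sm$upper)
  out <- data.frame(time = sm$time, S = S, ci_low = lo, ci_high = hi)
  structure(out, class = c("survival_curve", "data.frame"),
            n = nrow(records), n_events = sum(ev))
}

# usable points and inverse-variance weights from the CI half-width,
# measured in the space the fit runs in ("linear" for S(t) least squares,
# "log" for the semilog regression)
.curve_weights <- function(curve, space = c("linear", "log")) {
  space <- match.arg(space)
  hw <- if (space == "log")
    suppressWarnings((log(curve$ci_high) - log(curve$ci_low)) / 2)
  else (curve$ci_high - curve$ci_low) / 2
  usable <- curve$S > 0 & curve$S < 1 & curve$time > 0
  w_ok <- usable & is.finite(hw) & hw > 0
  if (sum(w_ok) >= 3) {
    list(idx = which(w_ok), w = 1 / hw[w_ok]^2, weighted = TRUE)
  } else {
    list(idx = which(usable), w = rep(1, sum(usable)), weighted = FALSE)
  }
}

#' Fit exponential decay components to a survival curve
#'
#' \code{n_components = 1}: weighted linear regression of \code{ln S} on
#' time through the origin (slope = -k).  \code{n_components > 1}: weighted
#' nonlinear least squares of \eqn{S(t) = \sum_i A_i e^{-k_i t}} with
#' \eqn{A_i > 0}, \eqn{\sum A_i = 1} (required by S(0) = 1), multi-start
#' initialization, deterministic for a given seed.  Points are weighted by
#' the inverse squared confidence-interval half-width, measured in the space
#' the fit runs in (log S for the semilog regression, S for multi-component
#' fits); the fit falls back to unweighted when the intervals are
#' degenerate (noiseless curves).
#'
#' @param curve a [km_survival()] result (or any data.frame with columns
#'   \code{time}, \code{S}, \code{ci_low}, \code{ci_high}).
#' @param n_components number of exponential components.
#' @param seed seed for the multi-start initialization.
#' @param n_starts number of random starts (multi-component fits).
#' @return object of class \code{"rate_estimate"}: \code{components}
#'   data.frame (A, k, k_err), \code{k} the effective rate [measurement()],
#'   \code{n_components}, \code{diagnostics}.
#' @export
fit_survival <- function(curve, n_components = 1, seed = 1, n_starts = 24) {
  cw <- .curve_weights(curve, space = if (n_components == 1) "log" else "linear")
  t <- curve$time[cw$idx]; S <- curve$S[cw$idx]; w <- cw$w
  if (length(t) < max(3, 3 * n_components))
    stop("need at least ", max(3, 3 * n_components),
         " grid points with 0 < S < 1")
  if (n_components == 1) {
    fit <- lm(log(S) ~ 0 + t, weights = w)
    k <- -unname(coef(fit)[1])
    if (k <= 0) stop("no decay: fitted rate is not positive")
    k_err <- unname(suppressWarnings(sqrt(diag(vcov(fit))))[1])
    est <- list(components = data.frame(A = 1, k = k, k_err = k_err),
                k = measurement(k, k_err), n_components = 1L,
                diagnostics = list(weighted = cw$weighted,
                                   rss = sum(w * (S - exp(-k * t))^2),
                                   n_points = length(t)))
    return(structure(est, class = "rate_estimate"))
  }
  n <- n_components
  # parameters: log k_1..k_n, logits a_1..a_{n-1} (softmax with last = 0)
  unpack <- function(th) {
    k <- exp(th[1:n])
    z <- c(th[(n + 1):(2 * n - 1)], 0)
    A <- exp(z - max(z)); A <- A / sum(A)
    list(A = A, k = k)
  }
  model <- function(th) {
    p <- unpack(th)
    as.vector(exp(-outer(t, p$k)) %*% p$A)
  }
  obj <- function(th) sum(w * (S - model(th))^2)
  t_scale <- 1 / stats::median(t)
  best <- NULL
  .with_seed(seed, for (s in seq_len(n_starts)) {
    th0 <- c(log(t_scale) + sort(runif(n, -3, 3), decreasing = TRUE),
             rnorm(n - 1, 0, 1))
    o <- tryCatch(optim(th0, obj, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  })
  if (is.null(best)) stop("multi-exponential fit failed to converge")
  p <- unpack(best$par)
  ord <- order(p$k, decreasing = TRUE)
  # covariance of the parameters: variance-known weighted least squares
  J <- pracma::jacobian(model, best$par)
  cov_th <- tryCatch(solve(t(J) %*% (w * J)), error = function(e) NULL)
  G <- pracma::jacobian(function(th) { q <- unpack(th); sum(q$A * q$k) },
                        matrix(best$par, nrow = 1))
  k_eff <- sum(p$A * p$k)
  k_eff_err <- if (is.null(cov_th)) NA_real_ else
    sqrt(max(0, as.numeric(G %*% cov_th %*% t(G))))
  k_errs <- if (is.null(cov_th)) rep(NA_real_, n) else
    sqrt(pmax(0, diag(cov_th)[1:n])) * p$k  # delta method for k = exp(theta)
  est <- list(components = data.frame(A = p$A[ord], k = p$k[ord],
                                      k_err = k_errs[ord]),
              k = measurement(k_eff, k_eff_err),
              n_components = as.integer(n),
              diagnostics = list(weighted = cw$weighted, rss = best$value,
                                 n_points = length(t),
                                 convergence = best$convergence))
  structure(est, class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("Rate estimate (", x$n_components, " component(s)): k =",
      format(x$k$value, digits = 4), "+-", format(x$k$sd, digits = 2), "s^-1\n")
  print(x$components)
  invisible(x)
}

#' Effective rate as the coefficient-weighted average of components
#'
#' \eqn{k = \sum_i A_i k_i / \sum_i A_i}, with the error propagated from
#' the fit covariance by first-order propagation.
#'
#' @param est a [fit_survival()] result (or any list with a
#'   \code{components} data.frame).
#' @return a [measurement()].
#' @export
effective_rate <- function(est) {
  co <- est$components
  stopifnot(all(co$A > 0), all(co$k > 0))
  measurement(sum(co$A * co$k) / sum(co$A),
              if (!is.null(est$k)) est$k$sd else NA_real_)
}

#' Select the number of exponential components by information criterion
#'
#' Fits 1..max_components and returns the admissible fit minimizing the
#' small-sample Akaike criterion (AICc) computed from the weighted residual
#' sum of squares.  A multi-component candidate is inadmissible (component
#' collapse) when any coefficient falls below \code{min_weight} or any rate
#' is statistically indistinguishable from zero (\code{k_err >= k}); all
#' candidates are kept in \code{$candidates}.
#'
#' @inheritParams fit_survival
#' @param max_components largest model to try (>= 1).
#' @param min_weight smallest admissible component coefficient.
#' @return the selected \code{"rate_estimate"} with a \code{candidates}
#'   data.frame attached.
#' @export
model_select <- function(curve, max_components = 3, seed = 1,
                         min_weight = 0.05) {
  stopifnot(max_components >= 1)
  fits <- list(); rows <- NULL
  for (n in seq_len(max_components)) {
    f <- tryCatch(fit_survival(curve, n, seed = seed), error = function(e) NULL)
    if (is.null(f)) next
    N <- f$diagnostics$n_points
    p <- 2 * n - 1
    if (N - p - 1 <= 0) next
    co <- f$components
    collapsed <- n > 1 && (any(co$A < min_weight) ||
                             any(is.finite(co$k_err) & co$k_err >= co$k))
    aicc <- N * log(f$diagnostics$rss / N) + 2 * p +
      2 * p * (p + 1) / (N - p - 1)
    fits[[as.character(n)]] <- f
    rows <- rbind(rows, data.frame(n_components = n, aicc = aicc,
                                   rss = f$diagnostics$rss,
                                   admissible = !collapsed))
  }
  if (is.null(rows) || !any(rows$admissible)) stop("no admissible fit converged")
  ok <- rows[rows$admissible, ]
  best <- ok$n_components[which.min(ok$aicc)]
  out <- fits[[as.character(best)]]
  out$candidates <- rows
  out
}
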