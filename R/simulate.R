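#' Configuration for overdamped Brownian dynamics
#'
#' @param D diffusion coefficient along the torsion, deg^2/s.
#' @param dt integration time step, s.  The per-step RMS random displacement
#'   \code{sqrt(2 D dt)} must stay below 1 degree (stability guard).
#' @param n_steps number of integration steps.
#' @param temperature temperature, K.
#' @param save_stride store every \code{save_stride}-th step.
#' @param seed integer seed for the trajectory RNG.
#' @return an object of class \code{"brownian_config"}.
#' @export
brownian_config <- function(D, dt, n_steps, temperature = 300,
                            save_stride = 1L, seed = 1L) {
  stopifnot(D > 0, dt > 0, n_steps >= 1, temperature > 0, save_stride >= 1,
            length(seed) == 1)
  if (sqrt(2 * D * dt) >= 1)
    stop("time step too large: per-step RMS displacement sqrt(2 D dt) = ",
         signif(sqrt(2 * D * dt), 3), " deg must be < 1 deg")
  structure(list(D = D, dt = dt, n_steps = as.numeric(n_steps),
                 temperature = temperature,
                 save_stride = as.integer(save_stride),
                 seed = as.numeric(seed)),
            class = "brownian_config")
}

#' Harmonic restraint on the torsion angle
#'
#' Restraint energy \code{0.5 * k * (omega - ref)^2} (minimal periodic image
#' of the difference), so that the stationary variance of an otherwise free
#' angle is \code{kB*T/k}.
#'
#' @param reference_omega reference angle, degrees.
#' @param force_constant force constant, kcal mol^-1 deg^-2 (>= 0).
#' @return an object of class \code{"restraint_spec"}.
#' @export
restraint_spec <- function(reference_omega, force_constant) {
  stopifnot(force_constant >= 0)
  structure(list(reference_omega = reference_omega,
                 force_constant = force_constant),
            class = "restraint_spec")
}

.new_trajectory <- function(times, omega, metadata) {
  structure(list(times = times, omega = omega, metadata = metadata),
            class = "trajectory_series")
}

#' @export
print.trajectory_series <- function(x, ...) {
  cat("Trajectory series:", length(x$omega), "samples, dt =",
      format(x$metadata$dt, digits = 4), "s, alpha =", x$metadata$alpha, "\n")
  if (!is.null(x$metadata$restraint))
    cat("  restraint: ref =", x$metadata$restraint$reference_omega,
        "deg, k =", x$metadata$restraint$force_constant, "\n")
  invisible(x)
}

#' Simulate overdamped diffusion on a torsion potential
#'
#' Euler-Maruyama integration of
#' \deqn{\omega \leftarrow \omega - \beta D \frac{dV}{d\omega} dt + \sqrt{2 D dt}\,\eta}
#' with standard-normal \eqn{\eta} and \eqn{V} the dihedral potential plus
#' (optionally) a harmonic restraint.  Trajectories are bit-reproducible for
#' a given seed.
#'
#' @param pot a [torsion_potential()].
#' @param cfg a [brownian_config()].
#' @param restraint optional [restraint_spec()].
#' @param start initial angle, degrees (default 180, the trans well).
#' @param stop_below,stop_above optional early-stop thresholds (degrees, on
#'   the wrapped coordinate): integration halts at the first step crossing
#'   the threshold, which is appended to the saved series.
#' @return a \code{"trajectory_series"}: uniform \code{times} (s), wrapped
#'   \code{omega} in [-90, 270), and metadata (alpha, dt, seed, D,
#'   temperature, restraint, stopped_at step or NA).
#' @export
simulate_overdamped <- function(pot, cfg, restraint = NULL, start = 180,
                                stop_below = NULL, stop_above = NULL) {
  stopifnot(inherits(pot, "torsion_potential"), inherits(cfg, "brownian_config"))
  if (!is.null(stop_below) && !is.null(stop_above))
    stop("only one of 'stop_below'/'stop_above' may be given")
  stop_mode <- 0L; stop_threshold <- 0
  if (!is.null(stop_below)) { stop_mode <- 1L; stop_threshold <- stop_below }
  if (!is.null(stop_above)) { stop_mode <- 2L; stop_threshold <- stop_above }
  has_r <- !is.null(restraint) && restraint$force_constant > 0
  res <- .bd_integrate(pot$terms, pot$alpha, pot$background,
                       start, cfg$D, 1 / kBT(cfg$temperature), cfg$dt,
                       cfg$n_steps, cfg$save_stride,
                       has_r,
                       if (has_r) restraint$reference_omega else 0,
                       if (has_r) restraint$force_constant else 0,
                       stop_mode, stop_threshold, cfg$seed)
  .new_trajectory(
    times = res$step * cfg$dt,
    omega = res$omega,
    metadata = list(alpha = pot$alpha, dt = cfg$dt * cfg$save_stride,
                    dt_step = cfg$dt, seed = cfg$seed, D = cfg$D,
                    temperature = cfg$temperature, restraint = restraint,
                    stopped_at = if (res$stopped_at < 0) NA_real_ else res$stopped_at,
                    final_phi = res$final_phi, kB = kB))
}

#' Generate a ladder of umbrella-sampling windows
#'
#' One restrained trajectory per reference angle; the initial condition of
#' window i+1 is the final state of window i (sequential chaining along the
#' ladder), each window discarding \code{n_equil} initial steps before
#' production.
#'
#' @param pot a [torsion_potential()].
#' @param window_refs reference angles, degrees; default 49 windows from -30
#'   to 210 in steps of 5.
#' @param k_production restraint force constant, kcal mol^-1 deg^-2
#'   (default 0.01).
#' @param cfg a [brownian_config()]; per-window seeds are derived from
#'   \code{cfg$seed}.
#' @param n_equil equilibration steps discarded at the start of each window.
#' @return list of \code{list(restraint, series)}, one per window.
#' @export
generate_umbrella_set <- function(pot, window_refs = seq(-30, 210, by = 5),
                                  k_production = 0.01, cfg, n_equil = 2000) {
  stopifnot(length(window_refs) >= 1)
  out <- vector("list", length(window_refs))
  state <- window_refs[1]
  for (i in seq_along(window_refs)) {
    r <- restraint_spec(window_refs[i], k_production)
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed + i * 7919  # distinct stream per window
    cfg_i$n_steps <- cfg$n_steps + n_equil
    class(cfg_i) <- "brownian_config"
    tr <- simulate_overdamped(pot, cfg_i, restraint = r, start = state)
    state <- tr$metadata$final_phi
    keep <- tr$times >= n_equil * cfg$dt
    tr$times <- tr$times[keep] - n_equil * cfg$dt
    tr$omega <- tr$omega[keep]
    out[[i]] <- list(restraint = r, series = tr)
  }
  out
}

#' Generate escape (first-passage) replicas from the trans well
#'
#' Independent replicas started in the trans conformation; each terminates
#' at its first detected crossing of \code{omega_ts} (at most one event per
#' replica) or runs to \code{cfg$n_steps} (censored).  Per-replica seeds are
#' derived from \code{cfg$seed} by index splitting.
#'
#' @param pot a [torsion_potential()].
#' @param n_replicas number of replicas (>= 1).
#' @param cfg a [brownian_config()].
#' @param start starting angle, degrees (default 180).
#' @param omega_ts transition-state angle used for early stopping, degrees.
#' @param direction \code{"trans_to_cis"} (event when omega drops below
#'   \code{omega_ts}) or \code{"cis_to_trans"}.
#' @return list of \code{"trajectory_series"}.
#' @export
generate_escape_replicas <- function(pot, n_replicas, cfg, start = 180,
                                     omega_ts = 90,
                                     direction = c("trans_to_cis", "cis_to_trans")) {
  direction <- match.arg(direction)
  stopifnot(n_replicas >= 1)
  lapply(seq_len(n_replicas), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- cfg$seed * 1000003 + i
    class(cfg_i) <- "brownian_config"
    if (direction == "trans_to_cis")
      simulate_overdamped(pot, cfg_i, start = start, stop_below = omega_ts)
    else
      simulate_overdamped(pot, cfg_i, start = start, stop_above = omega_ts)
  })
}
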