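# Shared fixture builders.  All sizes are desk scale: trajectories of
# 1e5-2e5 steps, D = 1e7 deg^2/s, per-step RMS displacement 0.5 deg.

std_cfg <- function(n_steps = 2e5, seed = 1, save_stride = 20, D = 1e7) {
  brownian_config(D = D, dt = 0.5^2 / (2 * D), n_steps = n_steps,
                  save_stride = save_stride, seed = seed)
}

double_well <- function(V2 = 8.4, alpha = 1, background = NULL) {
  torsion_potential(c(2, V2, 180), alpha = alpha, background = background)
}

# reconstruct the unwrapped coordinate from wrapped increments (valid while
# per-sample displacements stay well below 180 deg)
unwrap_series <- function(omega) {
  cumsum(c(omega[1], angle_diff(diff(omega))))
}

# independent product-limit + exponential-Greenwood implementation, used as
# the oracle for the survival module
km_oracle <- function(time, event, t_eval) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  ut <- unique(time[event == 1])
  S <- 1; v <- 0
  S_at <- rep(1, length(t_eval)); lo <- rep(1, length(t_eval)); hi <- rep(1, length(t_eval))
  for (t in ut) {
    n_i <- sum(time >= t)
    d_i <- sum(time == t & event == 1)
    S <- S * (1 - d_i / n_i)
    if (n_i > d_i) v <- v + d_i / (n_i * (n_i - d_i))
    after <- t_eval >= t
    S_at[after] <- S
    if (S > 0 && S < 1) {
      se <- sqrt(v / log(S)^2)
      lo[after] <- exp(-exp(log(-log(S)) + stats::qnorm(0.975) * se))
      hi[after] <- exp(-exp(log(-log(S)) - stats::qnorm(0.975) * se))
    } else {
      lo[after] <- S; hi[after] <- S
    }
  }
  data.frame(time = t_eval, S = S_at, ci_low = lo, ci_high = hi)
}
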