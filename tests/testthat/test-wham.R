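test_that("decorrelation time follows the two-fold 1/e rule", {
  dt <- 1e-9
  mk <- function(x) structure(list(times = seq_along(x) * dt, omega = x,
                                   metadata = list(dt = dt)),
                              class = "trajectory_series")
  set.seed(1)
  # white noise: first lag below 1/e is lag 1 -> two sampling intervals
  expect_equal(estimate_decorrelation(mk(rnorm(1e4))), 2 * dt)
  # AR(1) with correlation time tau = -1/log(rho) samples
  rho <- exp(-1 / 25)  # tau = 25 samples
  x <- as.vector(stats::arima.sim(list(ar = rho), 1e5))
  dec <- estimate_decorrelation(mk(x))
  expect_lt(abs(dec - 2 * 25 * dt) / (2 * 25 * dt), 0.2)
  expect_error(estimate_decorrelation(mk(rep(1, 500))), "constant")
  expect_error(estimate_decorrelation(mk(rnorm(50))), "short")
})

test_that("a single unbiased window on a flat potential gives a flat profile", {
  flat <- torsion_potential(c(2, 0, 180))
  tr <- simulate_overdamped(flat, std_cfg(4e5, seed = 12, save_stride = 10))
  win <- list(list(restraint = NULL, series = tr))
  pr <- bootstrap_profile_errors(win, decorrelation = estimate_decorrelation(tr))
  ok <- !is.na(pr$A) & !is.na(pr$A_err) & pr$counts >= 50
  expect_gt(sum(ok), 40)
  expect_true(all(pr$A[ok] <= 3 * sqrt(2) *
                    pmax(pr$A_err[ok], stats::median(pr$A_err[ok]))))
})

test_that("WHAM reproduces the quadrature Boltzmann profile on a double well", {
  pot <- double_well(8.4)
  win <- generate_umbrella_set(pot, cfg = std_cfg(1e5, seed = 21), n_equil = 4000)
  pr <- wham_solve(win)
  orc <- boltzmann_profile(pot)
  ok <- pr$counts >= 100 & !is.na(pr$A)
  d <- (pr$A - mean(pr$A[ok])) - (orc$A - mean(orc$A[ok]))
  expect_lt(sqrt(mean(d[ok]^2)), 0.15)
  expect_equal(min(pr$A, na.rm = TRUE), 0)   # anchoring
})

test_that("WHAM is consistent under window duplication and reordering", {
  pot <- double_well(3)
  win <- generate_umbrella_set(pot, window_refs = seq(0, 180, by = 20),
                               k_production = 0.02,
                               cfg = std_cfg(3e4, seed = 33), n_equil = 2000)
  pr <- wham_solve(win)
  # duplicated window pair vs concatenated samples in one window
  w1 <- win[[3]]
  cat2 <- w1
  cat2$series$omega <- rep(w1$series$omega, 2)
  cat2$series$times <- seq_along(cat2$series$omega) * w1$series$metadata$dt
  pr_dup <- wham_solve(c(win, list(w1)))
  pr_cat <- wham_solve(c(win[-3], list(cat2)))
  expect_equal(pr_dup$A, pr_cat$A, tolerance = 1e-6)
  # invariance under relabeling/reordering
  pr_rev <- wham_solve(rev(win))
  expect_equal(pr$A, pr_rev$A, tolerance = 1e-6)
})

test_that("disconnected windows are rejected", {
  pot <- double_well(2)
  win <- generate_umbrella_set(pot, window_refs = c(0, 180), k_production = 1,
                               cfg = std_cfg(5e3, seed = 9), n_equil = 500)
  expect_error(wham_solve(win), "disconnected")
})

test_that("bootstrap errors are reproducible and consistent with replication", {
  pot <- double_well(3)
  mk_win <- function(seed) generate_umbrella_set(
    pot, window_refs = seq(0, 180, by = 15), k_production = 0.02,
    cfg = std_cfg(3e4, seed = seed), n_equil = 2000)
  win <- mk_win(7)
  dec <- estimate_decorrelation(win[[5]]$series)
  e1 <- bootstrap_profile_errors(win, decorrelation = dec, n_trials = 2)
  e2 <- bootstrap_profile_errors(win, decorrelation = dec, n_trials = 2)
  expect_identical(e1$A_err, e2$A_err)
  expect_error(bootstrap_profile_errors(win, decorrelation = 1), "exceeds")
  # bootstrap SD within a factor 3 of the SD across independent datasets
  full <- bootstrap_profile_errors(win, decorrelation = dec)
  reps <- sapply(1:10, function(s) wham_solve(mk_win(100 + s))$A)
  truth <- apply(reps, 1, sd)
  st <- locate_states(full)
  # errors are relative to the anchor (the profile minimum), so compare at
  # the barrier and the non-anchor well
  idx <- c(st$idx_ts, st$idx_trans)
  ratio <- full$A_err[idx] / truth[idx]
  expect_true(all(ratio > 1 / 3 & ratio < 3))
})

test_that("state location finds wells and the transition state", {
  bins <- wham_bins()
  A <- 14 * (1 + cos((2 * bins$centers - 180) * pi / 180))
  pr <- free_energy_profile(bins$centers, A - min(A),
                            A_err = rep(0, 80), counts = rep(1000, 80),
                            alpha = 1, bins = bins)
  st <- locate_states(pr)
  expect_equal(st$omega_cis, 0)
  expect_equal(st$omega_ts, 90)
  expect_equal(st$omega_trans, 180)
  # shifted wells are detected at the shifted minima
  A2 <- 14 * (1 + cos((2 * (bins$centers + 5) - 180) * pi / 180)) +
    0.003 * bins$centers
  pr2 <- free_energy_profile(bins$centers, A2 - min(A2),
                             counts = rep(1000, 80), bins = bins)
  st2 <- locate_states(pr2)
  expect_lt(abs(st2$omega_cis - (-5)), 3.1)
  expect_lt(abs(st2$omega_trans - 175), 3.1)
  # monotone profile: no barrier
  pr3 <- free_energy_profile(bins$centers, 0.05 * (bins$centers + 31.5),
                             counts = rep(1000, 80), bins = bins)
  expect_error(locate_states(pr3), "monotone|no barrier")
})

test_that("barrier statistics match closed forms and obey the delta identity", {
  bins <- wham_bins()
  A <- 14 * (1 + cos((2 * bins$centers - 180) * pi / 180))
  pr <- free_energy_profile(bins$centers, A - min(A), A_err = rep(0.1, 80),
                            counts = rep(1000, 80), bins = bins)
  bs <- barrier_stats(pr)
  expect_equal(bs$dG_tc$value, 28, tolerance = 1e-9)
  expect_equal(bs$dG_ct$value, 28, tolerance = 1e-9)
  expect_equal(bs$dG_cis_trans$value, 0, tolerance = 1e-12)
  expect_equal(bs$dG_tc$value - bs$dG_ct$value, bs$dG_cis_trans$value,
               tolerance = 1e-12)
  expect_lt(bs$curv_ts$value, 0)
  expect_gt(bs$curv_trans$value, 0)
  expect_equal(bs$dG_tc$sd, sqrt(2) * 0.1)

  # asymmetric two-Gaussian-well profile: fitted curvatures vs analytic
  f <- function(w) 6 - 3 * exp(-w^2 / (2 * 25^2)) -
    5 * exp(-(w - 180)^2 / (2 * 30^2))
  d2f <- function(w) {
    g1 <- 3 / 25^2 * (1 - w^2 / 25^2) * exp(-w^2 / (2 * 25^2))
    g2 <- 5 / 30^2 * (1 - (w - 180)^2 / 30^2) * exp(-(w - 180)^2 / (2 * 30^2))
    g1 + g2
  }
  pr2 <- free_energy_profile(bins$centers, f(bins$centers) - min(f(bins$centers)),
                             counts = rep(1000, 80), bins = bins)
  bs2 <- barrier_stats(pr2, fit_halfwidth = 10)
  expect_lt(abs(bs2$curv_cis$value - d2f(bs2$states$omega_cis)) /
              abs(d2f(bs2$states$omega_cis)), 0.05)
  expect_lt(abs(bs2$curv_trans$value - d2f(bs2$states$omega_trans)) /
              abs(d2f(bs2$states$omega_trans)), 0.05)

  # unsampled interior bins abort rather than interpolate
  pr3 <- pr
  pr3$A[30] <- NA; pr3$counts[30] <- 0
  expect_error(barrier_stats(pr3), "interior")
})

test_that("the convergence trace is stationary for equilibrium data", {
  pot <- double_well(3)
  win <- generate_umbrella_set(pot, window_refs = seq(-20, 200, by = 10),
                               k_production = 0.06,
                               cfg = std_cfg(1e5, seed = 51), n_equil = 4000)
  dur <- max(win[[1]]$series$times)
  # stationarity threshold: twice the combined bootstrap uncertainty
  full <- bootstrap_profile_errors(win,
                                   decorrelation = estimate_decorrelation(win[[12]]$series))
  st <- locate_states(full)
  comb <- max(sqrt(full$A_err[st$idx_ts]^2 + full$A_err[st$idx_trans]^2),
              sqrt(full$A_err[st$idx_ts]^2 + full$A_err[st$idx_cis]^2))
  tr <- convergence_trace(win, block = dur / 4, threshold = 2 * comb)
  expect_equal(nrow(tr), 4)
  expect_true(all(diff(tr$time) > 0))
  expect_true(attr(tr, "converged"))
  one <- convergence_trace(win, block = dur * 0.9)
  expect_equal(nrow(one), 1)
})
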