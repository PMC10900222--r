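rotate_stack <- function(stack, angles = c(0.4, -0.8, 1.1), shift = c(3, -2, 5)) {
  cx <- cos(angles); sx <- sin(angles)
  Rx <- rbind(c(1, 0, 0), c(0, cx[1], -sx[1]), c(0, sx[1], cx[1]))
  Ry <- rbind(c(cx[2], 0, sx[2]), c(0, 1, 0), c(-sx[2], 0, cx[2]))
  Rz <- rbind(c(cx[3], -sx[3], 0), c(sx[3], cx[3], 0), c(0, 0, 1))
  R <- Rz %*% Ry %*% Rx
  co <- stack$coordinates
  for (f in seq_len(dim(co)[1]))
    co[f, , ] <- sweep(co[f, , ] %*% t(R), 2, -shift)
  ensemble_stack(co, stack$labels, stack$mask, stack$reference)
}

test_that("superposition removes rigid-body transforms exactly", {
  st <- generate_mode_ensembles(n_atoms = 20, window_refs = c(0, 90, 180),
                                frames_per_window = 5, coupling = 0.01,
                                noise_modes = 0, noise_sd = 0, seed = 2)
  # make every frame a rigid transform of frame 1
  co <- st$coordinates
  for (f in 2:dim(co)[1]) co[f, , ] <- co[1, , ]
  rigid <- rotate_stack(ensemble_stack(co, st$labels), c(0.2, 0.5, -0.3))
  rigid$coordinates[1, , ] <- co[1, , ]
  sup <- superpose_ensemble(rigid, reference = 1)
  rmsd <- sapply(2:dim(co)[1], function(f)
    sqrt(mean((sup$coordinates[f, , ] - sup$coordinates[1, , ])^2)))
  expect_true(all(rmsd < 1e-8))
  # superposing an already-aligned stack changes nothing materially
  st2 <- superpose_ensemble(st)
  st3 <- superpose_ensemble(st2)
  expect_equal(st3$coordinates, st2$coordinates, tolerance = 1e-8)
  # degenerate (collinear) atom sets are rejected
  line <- array(0, c(4, 3, 3))
  for (f in 1:4) line[f, , ] <- cbind(1:3, 0, 0) + f * 0.01
  expect_error(superpose_ensemble(ensemble_stack(line, labels = 1:4)),
               "degenerate")
})

test_that("PCA eigenvalues match a diagonal toy covariance", {
  # displacements only along atom-1 x (sd 2) and atom-1 y (sd 1)
  set.seed(5)
  n <- 40
  M <- scale(cbind(rnorm(n), rnorm(n)), scale = FALSE)
  q <- qr.Q(qr(M)) * sqrt(n - 1)  # exactly orthogonal, unit-sd, zero-mean
  co <- array(0, c(n, 2, 3))
  co[, 1, 1] <- 2 * q[, 1]
  co[, 1, 2] <- 1 * q[, 2]
  st <- ensemble_stack(co, labels = seq_len(n))
  pca <- multiensemble_pca(st)
  expect_equal(pca$sdev[1], 2, tolerance = 1e-6)
  expect_equal(pca$sdev[2], 1, tolerance = 1e-6)
  expect_equal(pca$variance_fraction[1], 0.8, tolerance = 1e-6)
  expect_equal(sum(pca$variance_fraction), 1)
})

test_that("PCA eigenvalues are invariant under global rotation", {
  st <- superpose_ensemble(generate_mode_ensembles(n_atoms = 15,
    window_refs = seq(0, 180, by = 45), frames_per_window = 12,
    coupling = 0.02, noise_modes = 2, noise_sd = 0.5, seed = 6))
  p1 <- multiensemble_pca(st)
  p2 <- multiensemble_pca(superpose_ensemble(rotate_stack(st)))
  k <- 10
  expect_equal(p1$sdev[1:k], p2$sdev[1:k], tolerance = 1e-6)
})

test_that("a dominant planted mode is recovered as PC1", {
  st <- generate_mode_ensembles(n_atoms = 30, frames_per_window = 20,
                                coupling = 0.05, noise_modes = 2,
                                noise_sd = 0.5, seed = 9)
  pca <- multiensemble_pca(superpose_ensemble(st))
  planted <- attr(st, "planted_mode")
  expect_gt(abs(sum(pca$loadings[, 1] * planted)), 0.95)
})

test_that("the functional PC is the highest-|rho| PC, not necessarily PC1", {
  # one high-variance noise mode uncorrelated with omega dominates PC1
  st <- generate_mode_ensembles(n_atoms = 40, frames_per_window = 30,
                                coupling = 0.015, noise_modes = 1,
                                noise_sd = 3, seed = 10)
  sup <- superpose_ensemble(st)
  pca <- multiensemble_pca(sup)
  fpc <- functional_pc(pca, sup$labels)
  expect_gt(abs(fpc$rho), 0.8)
  expect_gt(fpc$index, 1)
  expect_gt(abs(sum(fpc$vector * attr(st, "planted_mode"))), 0.9)
  # null fixture: no linear mode correlates with the labels
  null <- superpose_ensemble(generate_mode_ensembles(
    n_atoms = 50, window_refs = seq(-30, 210, length.out = 10),
    frames_per_window = 50, coupling = 0, noise_modes = 3, noise_sd = 1,
    seed = 11))
  fn <- functional_pc(multiensemble_pca(null), null$labels)
  expect_lt(abs(fn$rho), 0.2)
  expect_true(fn$low_signal)
})

test_that("PLS-FMA recovers a noiseless planted relation exactly", {
  st <- generate_mode_ensembles(n_atoms = 25, frames_per_window = 10,
                                coupling = 0.02, noise_modes = 0,
                                noise_sd = 0, seed = 12)
  fma <- pls_fma(st, n_components = 1)
  expect_equal(fma$rho, 1, tolerance = 1e-9)
  expect_gt(abs(sum(fma$vector * attr(st, "planted_mode"))), 0.99)
  expect_error(pls_fma(st, n_components = 1e4), "rank")
})

test_that("FMA correlation beats or ties the functional PC on noisy data", {
  st <- superpose_ensemble(generate_mode_ensembles(
    n_atoms = 40, frames_per_window = 30, coupling = 0.01,
    noise_modes = 4, noise_sd = 2, seed = 13))
  fma <- pls_fma(st, n_components = 2)
  fpc <- functional_pc(multiensemble_pca(st), st$labels)
  expect_gte(abs(fma$rho), abs(fpc$rho))
})

test_that("PLS with n = rank equals ordinary least squares", {
  set.seed(14)
  n <- 40; atoms <- 3
  co <- array(rnorm(n * atoms * 3), c(n, atoms, 3))
  y <- rnorm(n)
  st <- ensemble_stack(co, labels = y)
  fma <- pls_fma(st, n_components = 9)
  X <- t(sapply(seq_len(n), function(f) as.vector(t(co[f, , ]))))
  Xc <- scale(X, scale = FALSE)
  b_ols <- qr.solve(Xc, y - mean(y))
  expect_equal(fma$model$coef, as.vector(b_ols), tolerance = 1e-6)
})

test_that("cross-validation selects the generative dimension deterministically", {
  # one planted mode under isotropic noise: extra components only overfit
  st <- superpose_ensemble(generate_mode_ensembles(
    n_atoms = 30, frames_per_window = 25, coupling = 0.02,
    noise_modes = 0, noise_sd = 0.5, seed = 15))
  cv <- cross_validate_components(st, folds = 10, n_range = 1:4, seed = 20)
  expect_equal(cv$optimal_n, 1)
  cv2 <- cross_validate_components(st, folds = 10, n_range = 1:4, seed = 20)
  expect_identical(cv$cv_table, cv2$cv_table)

  # two independent planted score relations need two components
  set.seed(16)
  n <- 300; p <- 60
  m1 <- rnorm(p); m1 <- m1 / sqrt(sum(m1^2))
  m2 <- qr.Q(qr(cbind(m1, rnorm(p))))[, 2]
  t1 <- rnorm(n, 0, 1); t2 <- rnorm(n, 0, 6)
  X <- outer(t1, m1) + outer(t2, m2) + matrix(rnorm(n * p, 0, 0.05), n, p)
  y <- 40 * t1 + 2 * t2
  co <- array(0, c(n, p / 3, 3))
  for (ax in 1:3) co[, , ax] <- X[, seq(ax, p, 3)]
  st2 <- ensemble_stack(co, labels = y)
  cv3 <- cross_validate_components(st2, folds = 10, n_range = 1:4, seed = 21)
  expect_equal(cv3$optimal_n, 2)
})

test_that("mode sigma equals the projection standard deviation", {
  n <- 100
  st0 <- generate_mode_ensembles(n_atoms = 10, window_refs = c(0, 180),
                                 frames_per_window = n / 2, coupling = 0,
                                 noise_modes = 0, noise_sd = 0, seed = 17)
  v <- rnorm(30); v <- v / sqrt(sum(v^2))
  co <- st0$coordinates
  disp <- rep(c(1, -1), each = n / 2)
  for (ax in 1:3) co[, , ax] <- co[, , ax] + outer(disp, v[seq(ax, 30, 3)])
  st <- ensemble_stack(co, st0$labels)
  expect_equal(mode_sigma(st, v), sd(disp), tolerance = 1e-9)
  expect_equal(mode_sigma(st0, v), 0)
  # brute-force projection oracle on a mixed fixture
  stm <- generate_mode_ensembles(n_atoms = 10, frames_per_window = 10,
                                 noise_modes = 2, noise_sd = 0.7, seed = 18)
  X <- t(sapply(seq_len(dim(stm$coordinates)[1]),
                function(f) as.vector(t(stm$coordinates[f, , ]))))
  w <- rnorm(30); w <- w / sqrt(sum(w^2))
  expect_equal(mode_sigma(stm, w),
               sd(scale(X, scale = FALSE) %*% w), tolerance = 1e-10)
})

test_that("mode export filters arrows below the length threshold", {
  ref <- matrix(rnorm(30), 10, 3)
  v <- rep(1 / sqrt(30), 30)         # uniform loadings
  # each arrow has length scale * sqrt(3/30); pick scale so length = 2
  out <- export_mode_field(v, ref, scale = 2 / sqrt(3 / 30))
  expect_equal(nrow(out), 10)
  expect_equal(sqrt(out$dx^2 + out$dy^2 + out$dz^2), rep(2, 10))
  # all loadings below threshold: empty arrow set
  expect_equal(nrow(export_mode_field(v, ref, scale = 0.5)), 0)
  # mixed loadings equal a brute-force filter
  v2 <- rnorm(30)
  out2 <- export_mode_field(v2 / sqrt(sum(v2^2)), ref, scale = 6, min_arrow = 1)
  lens <- sqrt(rowSums(matrix(v2 / sqrt(sum(v2^2)), ncol = 3, byrow = TRUE)^2)) * 6
  expect_equal(out2$atom_index, which(lens >= 1))
  # file round trip
  f <- tempfile()
  export_mode_field(v2 / sqrt(sum(v2^2)), ref, scale = 6, file = f)
  expect_equal(read.table(f, header = TRUE)$dx, out2$dx, tolerance = 1e-6)
  expect_error(export_mode_field(v, ref[1:5, ]), "atom count")
})
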