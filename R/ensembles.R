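#' Labelled conformational ensemble stack
#'
#' @param coordinates numeric array frames x atoms x 3 (Angstrom).
#' @param labels reference omega per frame, degrees (>= 2 distinct values).
#' @param mask atom indices used for analysis (default all atoms).
#' @param reference reference structure, atoms x 3 matrix (default the mean
#'   over frames).
#' @return object of class \code{"ensemble_stack"}.
#' @export
ensemble_stack <- function(coordinates, labels, mask = NULL, reference = NULL) {
  d <- dim(coordinates)
  if (length(d) != 3 || d[3] != 3)
    stop("'coordinates' must be a frames x atoms x 3 array")
  if (length(labels) != d[1]) stop("every frame needs a label")
  if (length(unique(labels)) < 2) stop("need >= 2 distinct frame labels")
  if (is.null(mask)) mask <- seq_len(d[2])
  if (any(mask < 1 | mask > d[2])) stop("mask indices out of bounds")
  if (is.null(reference)) reference <- apply(coordinates, c(2, 3), mean)
  structure(list(coordinates = coordinates, labels = labels,
                 mask = as.integer(mask), reference = reference),
            class = "ensemble_stack")
}

#' @export
print.ensemble_stack <- function(x, ...) {
  d <- dim(x$coordinates)
  cat("Ensemble stack:", d[1], "frames,", d[2], "atoms,",
      length(unique(x$labels)), "distinct labels,",
      length(x$mask), "masked atoms\n")
  invisible(x)
}

# frames x 3m matrix (x1 y1 z1 x2 ...) over the masked atoms
.stack_xyz <- function(stack, masked = TRUE) {
  co <- stack$coordinates
  idx <- if (masked) stack$mask else seq_len(dim(co)[2])
  f <- dim(co)[1]
  out <- matrix(0, f, 3 * length(idx))
  out[, seq(1, ncol(out), 3)] <- co[, idx, 1]
  out[, seq(2, ncol(out), 3)] <- co[, idx, 2]
  out[, seq(3, ncol(out), 3)] <- co[, idx, 3]
  out
}

#' Generate pseudo-structure ensembles with a planted functional mode
#'
#' Emulates the pooled umbrella-window ensembles used for collective-mode
#' detection: each frame is the reference structure plus a displacement
#' along a planted unit mode proportional to the window's reference omega
#' (the functional signal), plus random-amplitude displacements along
#' orthogonal noise modes and small isotropic jitter.
#'
#' @param n_atoms number of atoms.
#' @param window_refs window reference angles (degrees), one per window.
#' @param frames_per_window frames generated per window.
#' @param planted_mode unit vector of length 3*n_atoms (random when NULL).
#' @param coupling displacement per degree along the planted mode, A/deg.
#' @param noise_modes number of orthogonal noise modes.
#' @param noise_sd standard deviation of the noise-mode amplitudes, A;
#'   isotropic jitter has sd \code{noise_sd/10}.
#' @param seed RNG seed.
#' @return an [ensemble_stack()] with attribute \code{"planted_mode"}.
#' @export
generate_mode_ensembles <- function(n_atoms = 50,
                                    window_refs = seq(-30, 210, by = 24),
                                    frames_per_window = 50,
                                    planted_mode = NULL,
                                    coupling = 0.02,
                                    noise_modes = 3,
                                    noise_sd = 1,
                                    seed = 1) {
  p <- 3 * n_atoms
  .with_seed(seed, {
    reference <- matrix(rnorm(p, sd = 5), n_atoms, 3)
    # rigid-body subspace of the reference (3 translations + 3 rotations):
    # planted and noise modes are internal motions, orthogonal to it, so
    # that least-squares superposition leaves them intact
    cen <- sweep(reference, 2, colMeans(reference))
    rigid <- matrix(0, p, 6)
    for (ax in 1:3) rigid[seq(ax, p, 3), ax] <- 1
    rot <- list(cbind(0, -cen[, 3], cen[, 2]),
                cbind(cen[, 3], 0, -cen[, 1]),
                cbind(-cen[, 2], cen[, 1], 0))
    for (j in 1:3) rigid[, 3 + j] <- as.vector(t(rot[[j]]))
    rigid_q <- qr.Q(qr(rigid))
    internalize <- function(v) {
      v <- v - rigid_q %*% crossprod(rigid_q, v)
      v / sqrt(sum(v^2))
    }
    if (is.null(planted_mode)) planted_mode <- rnorm(p)
    planted_mode <- as.vector(internalize(planted_mode))
    nm <- NULL
    if (noise_modes > 0) {
      nm <- matrix(rnorm(p * noise_modes), p, noise_modes)
      basis <- cbind(rigid_q, planted_mode, nm)
      nm <- qr.Q(qr(basis))[, -(1:7), drop = FALSE]  # internal, ortho to planted
    }
    labels <- rep(window_refs, each = frames_per_window)
    f <- length(labels)
    disp <- outer(coupling * (labels - mean(window_refs)), planted_mode)
    if (!is.null(nm)) {
      amps <- matrix(rnorm(f * ncol(nm), sd = noise_sd), f, ncol(nm))
      disp <- disp + amps %*% t(nm)
    }
    if (noise_sd > 0)
      disp <- disp + matrix(rnorm(f * p, sd = noise_sd / 10), f, p)
    co <- array(0, c(f, n_atoms, 3))
    for (ax in 1:3)
      co[, , ax] <- matrix(rep(reference[, ax], each = f), f, n_atoms) +
        disp[, seq(ax, p, 3)]
    st <- ensemble_stack(co, labels, reference = reference)
    attr(st, "planted_mode") <- planted_mode
    st
  })
}
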