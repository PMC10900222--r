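#' Collective-mode result container
#'
#' @param vector unit-norm loading vector (length 3 x masked atoms,
#'   interleaved x, y, z per atom).
#' @param rho Pearson correlation between the per-frame projection (or
#'   model prediction) and the frame labels omega.
#' @param sigma standard deviation of conformations along the mode, A.
#' @param variance_fraction fraction of total variance (PCA modes).
#' @param n_components PLS component count (PLS modes).
#' @param index PC index (PCA modes).
#' @param method \code{"pca"} or \code{"pls_fma"}.
#' @return object of class \code{"mode_result"}.
#' @export
mode_result <- function(vector, rho, sigma, variance_fraction = NA_real_,
                        n_components = NA_integer_, index = NA_integer_,
                        method = c("pca", "pls_fma")) {
  method <- match.arg(method)
  nv <- sqrt(sum(vector^2))
  if (abs(nv - 1) > 1e-8) vector <- vector / nv
  stopifnot(rho >= -1 - 1e-12, rho <= 1 + 1e-12, sigma >= 0)
  structure(list(vector = vector, rho = rho, sigma = sigma,
                 variance_fraction = variance_fraction,
                 n_components = n_components, index = index, method = method,
                 low_signal = abs(rho) < 0.2),
            class = "mode_result")
}

#' @export
print.mode_result <- function(x, ...) {
  cat("Collective mode (", x$method, "): rho =", format(x$rho, digits = 3),
      ", sigma =", format(x$sigma, digits = 3), "A",
      if (!is.na(x$index)) paste0(", PC", x$index) else "",
      if (x$low_signal) " [low signal]" else "", "\n", sep = "")
  invisible(x)
}

# xyz column indices of the masked atoms in the full interleaved matrix
.mask_xyz_idx <- function(mask) {
  as.vector(t(outer(3 * (mask - 1), 1:3, `+`)))
}

#' Least-squares superposition of an ensemble
#'
#' Rigidly rotates/translates every frame to minimize the RMSD to the
#' reference over the masked atoms (Kabsch superposition via
#' \code{bio3d::fit.xyz}).  The default reference is the mean structure,
#' obtained by a fit to the stack reference followed by a re-fit to the
#' resulting mean.
#'
#' @param stack an [ensemble_stack()].
#' @param reference \code{"mean"} or a frame index.
#' @return the superposed [ensemble_stack()].
#' @export
superpose_ensemble <- function(stack, reference = "mean") {
  co <- stack$coordinates
  f <- dim(co)[1]; m <- dim(co)[2]
  refm <- stack$reference[stack$mask, , drop = FALSE]
  sv <- svd(scale(refm, center = TRUE, scale = FALSE))$d
  if (length(stack$mask) < 3 || sum(sv > 1e-8) < 2)
    stop("degenerate (collinear) masked atom set")
  xyz <- .stack_xyz(stack, masked = FALSE)
  mi <- .mask_xyz_idx(stack$mask)
  fit_to <- function(ref_xyz) {
    bio3d::fit.xyz(fixed = ref_xyz, mobile = xyz,
                   fixed.inds = mi, mobile.inds = mi)
  }
  if (identical(reference, "mean")) {
    xyz <- fit_to(as.vector(t(stack$reference)))
    xyz <- fit_to(colMeans(xyz))
  } else {
    xyz <- fit_to(xyz[reference, ])
  }
  out <- array(0, dim(co))
  for (ax in 1:3) out[, , ax] <- xyz[, seq(ax, 3 * m, 3)]
  res <- ensemble_stack(out, stack$labels, stack$mask,
                        apply(out, c(2, 3), mean))
  attr(res, "planted_mode") <- attr(stack, "planted_mode")
  res
}

#' Multiensemble principal component analysis
#'
#' Eigen-decomposition of the pooled Cartesian covariance of the masked
#' atoms over all windows' frames (superpose first); modes are sorted by
#' descending eigenvalue.
#'
#' @param stack a superposed [ensemble_stack()].
#' @return object of class \code{"multiensemble_pca"}: unit \code{loadings}
#'   (columns), \code{sdev}, per-frame \code{scores},
#'   \code{variance_fraction} (sums to 1), \code{center}.
#' @export
multiensemble_pca <- function(stack) {
  X <- .stack_xyz(stack)
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < ncol(X))
    message("rank-deficient covariance: retained ", ncol(pc$rotation),
            " of ", ncol(X), " modes")
  lam <- pc$sdev^2
  structure(list(loadings = pc$rotation, sdev = pc$sdev, scores = pc$x,
                 variance_fraction = lam / sum(lam), center = pc$center),
            class = "multiensemble_pca")
}

#' Select the functional principal component
#'
#' Among the first \code{top_n} PCs, returns the one whose per-frame
#' projection has the largest absolute Pearson correlation with the frame
#' labels omega.
#'
#' @param pca a [multiensemble_pca()] result.
#' @param labels per-frame omega labels.
#' @param top_n number of leading PCs searched (default 10).
#' @return a [mode_result()]; \code{low_signal} is set when |rho| < 0.2.
#' @export
functional_pc <- function(pca, labels, top_n = 10) {
  stopifnot(top_n >= 1)
  k <- min(top_n, ncol(pca$scores))
  rho <- sapply(seq_len(k), function(i) cor(pca$scores[, i], labels))
  i <- which.max(abs(rho))
  mode_result(pca$loadings[, i], rho[i], pca$sdev[i],
              variance_fraction = pca$variance_fraction[i],
              index = i, method = "pca")
}

# PLS1 (NIPALS): returns coefficient vector and loadings for n components
.pls1 <- function(X, y, n_components) {
  E <- X; f <- y
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { n_components <- a - 1; break }
    w <- w / nw
    t_ <- E %*% w
    tt <- sum(t_^2)
    P[, a] <- crossprod(E, t_) / tt
    q[a] <- sum(f * t_) / tt
    W[, a] <- w
    E <- E - t_ %*% t(P[, a])
    f <- f - q[a] * t_
  }
  if (n_components < 1) stop("response has no covariance with the coordinates")
  W <- W[, seq_len(n_components), drop = FALSE]
  P <- P[, seq_len(n_components), drop = FALSE]
  q <- q[seq_len(n_components)]
  b <- W %*% solve(crossprod(P, W), q)
  list(coef = as.vector(b), n_components = n_components)
}

#' Partial-least-squares functional mode analysis (multiensemble FMA)
#'
#' PLS1 regression of the frame labels omega on the centered masked
#' coordinates of the pooled ensembles; the functional mode is the
#' unit-normalized regression coefficient vector mapped back to coordinate
#' space, and the model predicts omega per frame.  The reported rho is the
#' Pearson correlation between predicted and reference omega.
#'
#' @param stack a superposed [ensemble_stack()].
#' @param labels per-frame omega (defaults to the stack labels).
#' @param n_components number of PLS components (<= rank of the data).
#' @return a [mode_result()] with the fitted \code{model} (coefficients and
#'   centers) and per-frame \code{predicted} values attached.
#' @export
pls_fma <- function(stack, labels = stack$labels, n_components = 1) {
  X <- .stack_xyz(stack)
  if (n_components > min(nrow(X) - 1, ncol(X)))
    stop("n_components exceeds the rank of the data")
  xc <- colMeans(X); yc <- mean(labels)
  fit <- .pls1(sweep(X, 2, xc), labels - yc, n_components)
  pred <- as.vector(sweep(X, 2, xc) %*% fit$coef) + yc
  rho <- cor(pred, labels)
  mr <- mode_result(fit$coef, rho, .proj_sd(X, fit$coef),
                    n_components = fit$n_components, method = "pls_fma")
  mr$model <- list(coef = fit$coef, x_center = xc, y_center = yc)
  mr$predicted <- pred
  mr
}

.proj_sd <- function(X, v) {
  v <- v / sqrt(sum(v^2))
  sd(as.vector(sweep(X, 2, colMeans(X)) %*% v))
}

#' Cross-validated choice of the PLS component count
#'
#' Seeded random partition of the frames into folds; for each candidate
#' component count the mean test-fold Pearson correlation between predicted
#' and reference omega is computed, the argmax is returned, and the final
#' model is refit on all frames.  Leave-window-out partitioning (folds =
#' distinct labels) is available since random frame folds can leak window
#' structure.
#'
#' @param stack a superposed [ensemble_stack()].
#' @param labels per-frame omega (defaults to the stack labels).
#' @param folds number of folds (>= 2).
#' @param n_range candidate component counts.
#' @param seed RNG seed for the fold assignment.
#' @param by_window partition by distinct label instead of at random.
#' @return list: \code{optimal_n}, \code{cv_table} (n, mean test
#'   correlation), \code{final} the refit [pls_fma()] model.
#' @export
cross_validate_components <- function(stack, labels = stack$labels,
                                      folds = 10, n_range = 1:5, seed = 1,
                                      by_window = FALSE) {
  stopifnot(folds >= 2)
  X <- .stack_xyz(stack)
  f <- nrow(X)
  assign_f <- if (by_window) {
    u <- unique(labels)
    grp <- match(labels, u)
    ((grp - 1) %% folds) + 1
  } else {
    .with_seed(seed, sample(rep(seq_len(folds), length.out = f)))
  }
  if (min(table(assign_f)) < 2) stop("a fold has fewer than 2 frames")
  n_range <- n_range[n_range <= min(f - ceiling(f / folds) - 1, ncol(X))]
  cv <- sapply(n_range, function(n) {
    cors <- sapply(seq_len(folds), function(k) {
      tr <- assign_f != k; te <- !tr
      xc <- colMeans(X[tr, , drop = FALSE]); yc <- mean(labels[tr])
      fit <- .pls1(sweep(X[tr, , drop = FALSE], 2, xc), labels[tr] - yc, n)
      pred <- as.vector(sweep(X[te, , drop = FALSE], 2, xc) %*% fit$coef) + yc
      if (sd(pred) == 0 || sd(labels[te]) == 0) return(NA_real_)
      cor(pred, labels[te])
    })
    mean(cors, na.rm = TRUE)
  })
  optimal_n <- n_range[which.max(cv)]
  list(optimal_n = optimal_n,
       cv_table = data.frame(n_components = n_range, test_correlation = cv),
       final = pls_fma(stack, labels, optimal_n))
}

#' Standard deviation of conformations along a mode
#'
#' @param stack a superposed [ensemble_stack()].
#' @param vector mode vector over the masked atoms (normalized internally).
#' @return sigma in A.
#' @export
mode_sigma <- function(stack, vector) {
  .proj_sd(.stack_xyz(stack), vector)
}

#' Export a mode as a per-atom displacement field
#'
#' Per-atom arrows scaled by the mode loadings, dropping arrows shorter
#' than \code{min_arrow} (the conventional porcupine-plot clarity filter);
#' optionally written as a whitespace-delimited text file
#' \code{atom_index x y z dx dy dz}.
#'
#' @param mode a [mode_result()] (or a raw loading vector).
#' @param reference_structure atoms x 3 matrix matching the mode length.
#' @param scale multiplier applied to the loadings, A.
#' @param min_arrow minimum arrow length kept, A (default 1).
#' @param file optional output path.
#' @return data.frame of the retained arrows (invisibly when writing).
#' @export
export_mode_field <- function(mode, reference_structure, scale = 1,
                              min_arrow = 1, file = NULL) {
  v <- if (inherits(mode, "mode_result")) mode$vector else mode
  m <- length(v) / 3
  if (m != nrow(reference_structure))
    stop("mode length does not match the reference atom count")
  d <- matrix(v, ncol = 3, byrow = TRUE) * scale
  len <- sqrt(rowSums(d^2))
  keep <- len >= min_arrow
  out <- data.frame(atom_index = which(keep),
                    x = reference_structure[keep, 1],
                    y = reference_structure[keep, 2],
                    z = reference_structure[keep, 3],
                    dx = d[keep, 1], dy = d[keep, 2], dz = d[keep, 3])
  if (!is.null(file)) {
    write.table(out, file, quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
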