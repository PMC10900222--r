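# Ensemble-stack interchange: coordinates as whitespace-delimited text (one
# row per frame, 3m columns), labels as `frame_index omega_ref_deg`, and the
# reference structure as PDB (via bio3d).

#' Write / read an ensemble stack
#'
#' Writes three sibling files: \code{<basename>.crd} (one row of
#' interleaved x y z coordinates per frame), \code{<basename>.labels}
#' (\code{frame_index omega_ref_deg}) and \code{<basename>.pdb} (the
#' reference structure, C-alpha pseudo-atoms).
#'
#' @param stack an [ensemble_stack()].
#' @param basename path prefix for the three files.
#' @return the basename, invisibly; \code{read_ensemble} returns an
#'   [ensemble_stack()].
#' @export
write_ensemble <- function(stack, basename) {
  xyz <- .stack_xyz(stack, masked = FALSE)
  write.table(xyz, paste0(basename, ".crd"), row.names = FALSE,
              col.names = FALSE)
  write.table(data.frame(seq_along(stack$labels), stack$labels),
              paste0(basename, ".labels"), row.names = FALSE,
              col.names = c("frame_index", "omega_ref_deg"), quote = FALSE)
  n <- nrow(stack$reference)
  bio3d::write.pdb(file = paste0(basename, ".pdb"),
                   xyz = as.vector(t(stack$reference)),
                   resno = seq_len(n), resid = rep("GLY", n),
                   elety = rep("CA", n))
  invisible(basename)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(basename) {
  xyz <- as.matrix(read.table(paste0(basename, ".crd")))
  lab <- read.table(paste0(basename, ".labels"), header = TRUE)
  ref <- bio3d::read.pdb(paste0(basename, ".pdb"))
  m <- ncol(xyz) / 3
  co <- array(0, c(nrow(xyz), m, 3))
  for (ax in 1:3) co[, , ax] <- xyz[, seq(ax, 3 * m, 3)]
  ensemble_stack(co, lab$omega_ref_deg,
                 reference = matrix(ref$xyz, ncol = 3, byrow = TRUE))
}

#' Serialize a collective mode as JSON
#'
#' @param mode a [mode_result()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_mode <- function(mode, file) {
  jsonlite::write_json(list(method = mode$method, rho = mode$rho,
                            sigma = mode$sigma,
                            variance_fraction = mode$variance_fraction,
                            n_components = mode$n_components,
                            index = mode$index, vector = mode$vector),
                       file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' Serialize a Kramers fit as JSON
#'
#' Records the per-point inputs, the intercept, the effective diffusion
#' coefficient with its error, the temperature and the constants used.
#'
#' @param fit a [kramers_regression()] result.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_kramers_fit <- function(fit, file) {
  jsonlite::write_json(list(
    alpha = fit$points$alpha, y = fit$y, y_err = fit$y_err,
    intercept = fit$intercept$value, intercept_err = fit$intercept$sd,
    D_eff = fit$D_eff$value, D_eff_err = fit$D_eff$sd,
    temperature = fit$temperature, kB = kB, weighted = fit$weighted),
    file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
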