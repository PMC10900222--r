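#' A value with a standard deviation
#'
#' @param value numeric value.
#' @param sd standard deviation (>= 0, or NA when unknown).
#' @return object of class \code{"measurement"}.
#' @export
measurement <- function(value, sd = NA_real_) {
  stopifnot(is.numeric(value), length(value) == 1)
  if (!is.na(sd) && sd < 0) stop("'sd' must be >= 0")
  structure(list(value = value, sd = sd), class = "measurement")
}

#' @export
print.measurement <- function(x, ...) {
  cat(format(x$value, digits = 4), "+-", format(x$sd, digits = 2), "\n")
  invisible(x)
}

#' First-order (delta-method) error propagation
#'
#' For \eqn{f(x, y, \ldots)} with independent inputs,
#' \deqn{s_f = \sqrt{\sum_i (\partial f/\partial x_i)^2 s_{x_i}^2}.}
#'
#' @param derivatives partial derivatives of f at the evaluation point.
#' @param sds standard deviations of the inputs (same length).
#' @return propagated standard deviation.
#' @examples
#' propagate_error(c(1, -1), c(0.52, 0.51)) # difference of two values
#' @export
propagate_error <- function(derivatives, sds) {
  stopifnot(length(derivatives) == length(sds))
  if (any(!is.na(sds) & sds < 0)) stop("standard deviations must be >= 0")
  sqrt(sum(derivatives^2 * sds^2))
}

# evaluate expr under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
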