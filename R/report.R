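# half-away-from-zero rounding, applied only at the reporting boundary;
# the inner round() guards against binary representation of decimal inputs
# (e.g. 21.24 - 20.39 = 0.8499999...) dropping below the half-way mark
.round_half_away <- function(x, decimals = 0) {
  s <- 10^decimals
  sign(x) * floor(round(abs(x) * s, 9) + 0.5) / s
}

#' Per-system summary of free energies, rates and diffusion coefficient
#'
#' One row per barrier scaling (the modified-potential measurements) plus
#' exactly one real-potential row (\code{alpha = 1}) that also carries the
#' effective diffusion coefficient; the \code{provenance} column records
#' whether each row comes from direct sampling or from the extrapolation
#' scheme.
#'
#' @param system system name.
#' @param rows data.frame with columns \code{V2}, \code{alpha},
#'   \code{dG_tc}, \code{dG_tc_err}, \code{dG_ct}, \code{dG_ct_err},
#'   \code{dG_cis_trans}, \code{dG_cis_trans_err}, \code{k}, \code{k_err},
#'   \code{D_eff}, \code{D_eff_err}, \code{provenance}.
#' @return data.frame of class \code{"system_summary"}.
#' @export
system_summary <- function(system, rows) {
  need <- c("V2", "alpha", "dG_tc", "dG_tc_err", "dG_ct", "dG_ct_err",
            "dG_cis_trans", "dG_cis_trans_err", "k", "k_err",
            "D_eff", "D_eff_err", "provenance")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (sum(rows$alpha == 1) != 1)
    stop("exactly one real-potential (alpha = 1) row is required")
  errs <- unlist(rows[grep("_err$", names(rows))])
  if (any(!is.na(errs) & errs < 0)) stop("errors must be >= 0")
  out <- cbind(system = system, rows[need])
  out <- out[order(out$alpha), ]
  class(out) <- c("system_summary", "data.frame")
  out
}

#' Assemble and serialize the multi-system summary table
#'
#' @param summaries list of [system_summary()] data.frames (or one combined
#'   data.frame with a \code{system} column).
#' @param file optional path; written as tab-delimited text (a sibling
#'   \code{.json} with full precision is written alongside).
#' @return the combined data.frame, deterministically ordered by system
#'   then alpha.
#' @export
summary_table <- function(summaries, file = NULL) {
  if (is.data.frame(summaries)) summaries <- split(summaries, summaries$system)
  if (length(summaries) == 0) {
    warning("empty input: empty summary table")
    return(data.frame())
  }
  summaries <- lapply(names(summaries), function(nm) {
    s <- summaries[[nm]]
    if (inherits(s, "system_summary")) s else system_summary(nm, s)
  })
  out <- do.call(rbind, lapply(summaries, as.data.frame))
  out <- out[order(out$system, out$alpha), ]
  rownames(out) <- NULL
  if (!is.null(file)) {
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(out, sub("\\.[^.]*$", "", file), digits = NA)
  }
  out
}

#' Load the bundled reference isomerization table
#'
#' Literature-derived free-energy, rate and diffusion measurements for the
#' FFpSPR substrate peptide free in solution and bound to Pin1 constructs
#' (two free peptides and four complexes; per-alpha reduced-barrier rows
#' plus the real-potential row per system), used as input to the
#' comparative report.
#'
#' @return data.frame with one row per (system, alpha).
#' @export
reference_summaries <- function() {
  path <- system.file("extdata", "pin1_isomerization_reference.tsv",
                      package = "allokin")
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

# pull a quantity off a system's real-potential row as a measurement
.real_row_measurement <- function(summaries, system, quantity) {
  r <- summaries[summaries$system == system & summaries$alpha == 1, ]
  if (nrow(r) != 1) stop("no real-potential row for system '", system, "'")
  if (!quantity %in% names(r)) stop("unknown quantity '", quantity, "'")
  measurement(r[[quantity]], r[[paste0(quantity, "_err")]])
}

#' Difference of two measurements with propagated error
#'
#' \code{value = a - b}, \code{sd = sqrt(sa^2 + sb^2)}; both rounded
#' half-away-from-zero to \code{decimals} for display, full precision kept.
#'
#' @param a,b [measurement()]s.
#' @param decimals display decimals (default 1).
#' @return one-row data.frame: raw and rounded value and sd.
#' @export
delta_with_error <- function(a, b, decimals = 1) {
  v <- a$value - b$value
  s <- propagate_error(c(1, -1), c(a$sd, b$sd))
  data.frame(type = "delta", value_raw = v, sd_raw = s,
             value = .round_half_away(v, decimals),
             sd = .round_half_away(s, decimals))
}

#' Fold change of two measurements
#'
#' @param a,b [measurement()]s; \code{b$value} must be positive.
#' @return one-row data.frame with the raw ratio and the nearest-integer
#'   fold.
#' @export
fold_change <- function(a, b) {
  if (b$value <= 0) stop("denominator must be positive")
  r <- a$value / b$value
  data.frame(type = "fold", value_raw = r, sd_raw = NA_real_,
             value = .round_half_away(r, 0), sd = NA_real_)
}

#' Default comparative plan for the bundled reference systems
#'
#' The pairwise deltas (with propagated errors) and fold changes between
#' the real-potential rows of the six reference systems: phosphorylation
#' effect in free peptides, catalytic-domain effect, the effect of adding
#' and of loading the substrate-binding domain, and the diffusion-
#' coefficient folds.
#'
#' @return data.frame plan consumed by [comparison_report()].
#' @export
default_comparison_plan <- function() {
  p <- rbind(
    c("delta", "dG_ct", "FFpSPR", "FFSPR", "phosphorylation raises the cis->trans barrier"),
    c("delta", "dG_tc", "FFpSPR", "FFSPR", "phosphorylation raises the trans->cis barrier"),
    c("delta", "dG_tc", "FFpSPR", "FFpSPR-PPIase", "catalytic domain lowers the trans->cis barrier"),
    c("delta", "dG_tc", "FFpSPR-PPIase", "FFpSPR-Pin1", "adding the binding domain lowers the trans->cis barrier"),
    c("fold",  "k", "FFpSPR-Pin1", "FFpSPR-PPIase", "adding the binding domain raises the rate"),
    c("delta", "dG_cis_trans", "FFpSPR-FFpSPR", "FFpSPR", "substrate in the binding domain stabilizes trans"),
    c("delta", "dG_tc", "FFpSPR-FFpSPR", "FFpSPR-Pin1", "substrate in the binding domain raises the trans->cis barrier"),
    c("delta", "dG_ct", "FFpSPR-Pin1", "FFpSPR-FFpSPR", "substrate in the binding domain lowers the cis->trans barrier"),
    c("delta", "dG_tc", "FFpSPR-Pin1", "FFpSPR-pTPP", "effector peptide lowers the trans->cis barrier"),
    c("delta", "dG_ct", "FFpSPR-Pin1", "FFpSPR-pTPP", "effector peptide lowers the cis->trans barrier"),
    c("fold",  "k", "FFpSPR-Pin1", "FFpSPR-pTPP", "effector peptide reduces the rate"),
    c("fold",  "D_eff", "FFpSPR-Pin1", "FFpSPR-PPIase", "adding the binding domain enhances diffusion"),
    c("fold",  "D_eff", "FFpSPR-Pin1", "FFpSPR-FFpSPR", "substrate in the binding domain reduces diffusion"),
    c("fold",  "D_eff", "FFpSPR-Pin1", "FFpSPR-pTPP", "effector peptide reduces diffusion"))
  data.frame(type = p[, 1], quantity = p[, 2], system_a = p[, 3],
             system_b = p[, 4], label = p[, 5], decimals = 1,
             stringsAsFactors = FALSE)
}

#' Execute a plan of comparative deltas and fold changes
#'
#' Each plan row compares a quantity between the real-potential rows of two
#' systems; inputs are echoed alongside every result so that each reported
#' number is reproducible by a one-line recomputation.
#'
#' @param summaries combined summary data.frame (see [summary_table()],
#'   [reference_summaries()]).
#' @param plan data.frame with columns \code{type} ("delta"/"fold"),
#'   \code{quantity}, \code{system_a}, \code{system_b}, optionally
#'   \code{label} and \code{decimals}.
#' @return data.frame, one row per plan entry, in plan order.
#' @export
comparison_report <- function(summaries, plan = default_comparison_plan()) {
  if (nrow(plan) == 0) return(data.frame())
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    a <- .real_row_measurement(summaries, p$system_a, p$quantity)
    b <- .real_row_measurement(summaries, p$system_b, p$quantity)
    res <- if (p$type == "delta")
      delta_with_error(a, b, if (is.null(p$decimals)) 1 else p$decimals)
    else if (p$type == "fold") fold_change(a, b)
    else stop("unknown comparison type '", p$type, "'")
    cbind(quantity = p$quantity, system_a = p$system_a,
          system_b = p$system_b,
          label = if ("label" %in% names(p)) p$label else NA,
          res,
          a_value = a$value, a_sd = a$sd, b_value = b$value, b_sd = b$sd)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
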