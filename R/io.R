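# Delimited-text interchange formats: trajectory series, free-energy
# profiles and event tables, each with '#'-prefixed metadata headers.

#' Write / read a trajectory series
#'
#' Two columns \code{time_s omega_deg}; header comments carry alpha, dt,
#' seed and the restraint, so a round trip preserves the metadata the
#' downstream stages need.
#'
#' @param series a \code{"trajectory_series"}.
#' @param file path.
#' @return \code{write_trajectory}: the path, invisibly;
#'   \code{read_trajectory}: a \code{"trajectory_series"}.
#' @export
write_trajectory <- function(series, file) {
  md <- series$metadata
  hdr <- c(paste("# alpha", md$alpha),
           paste("# dt_s", format(md$dt, digits = 17)),
           paste("# seed", md$seed),
           if (!is.null(md$restraint))
             c(paste("# restraint_ref_deg", md$restraint$reference_omega),
               paste("# restraint_k", md$restraint$force_constant)))
  writeLines(c(hdr, "# time_s omega_deg"), file)
  write.table(data.frame(series$times, series$omega), file,
              append = TRUE, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(file) {
  lines <- readLines(file)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    m <- hdr[grepl(paste0("^# ", key, " "), hdr)]
    if (!length(m)) return(NULL)
    as.numeric(sub(paste0("^# ", key, " "), "", m[1]))
  }
  d <- read.table(file, comment.char = "#")
  restraint <- if (!is.null(get("restraint_ref_deg")))
    restraint_spec(get("restraint_ref_deg"), get("restraint_k"))
  .new_trajectory(d[[1]], d[[2]],
                  metadata = list(alpha = get("alpha"), dt = get("dt_s"),
                                  seed = get("seed"), restraint = restraint,
                                  kB = kB))
}

#' Write / read a free-energy profile
#'
#' Columns \code{bin_center_deg A_kcal_mol A_err_kcal_mol counts}; header
#' comments carry alpha and temperature.  Unsampled bins are stored as NA.
#'
#' @param profile a [free_energy_profile()].
#' @param file path.
#' @return \code{write_profile}: the path, invisibly;
#'   \code{read_profile}: a [free_energy_profile()].
#' @export
write_profile <- function(profile, file) {
  writeLines(c(paste("# alpha", profile$alpha),
               paste("# temperature_K", profile$temperature),
               "# bin_center_deg A_kcal_mol A_err_kcal_mol counts"), file)
  write.table(data.frame(profile$bin_centers, profile$A, profile$A_err,
                         profile$counts),
              file, append = TRUE, col.names = FALSE, row.names = FALSE,
              quote = FALSE)
  invisible(file)
}

#' @rdname write_profile
#' @export
read_profile <- function(file) {
  lines <- readLines(file, n = 20)
  get <- function(key) {
    m <- lines[grepl(paste0("^# ", key, " "), lines)]
    if (!length(m)) return(NA_real_)
    as.numeric(sub(paste0("^# ", key, " "), "", m[1]))
  }
  d <- read.table(file, comment.char = "#")
  centers <- d[[1]]
  w <- diff(centers)[1]
  free_energy_profile(centers, d[[2]], d[[3]], counts = d[[4]],
                      alpha = get("alpha"),
                      temperature = get("temperature_K"),
                      bins = wham_bins(length(centers),
                                       centers[1] - w / 2,
                                       centers[length(centers)] + w / 2))
}

#' Write / read an event table
#'
#' Columns \code{replica_id time_s status}.
#'
#' @param records event data.frame (see [event_records()]).
#' @param file path.
#' @return \code{write_events}: the path invisibly; \code{read_events}:
#'   the data.frame.
#' @export
write_events <- function(records, file) {
  write.table(setNames(records, c("replica_id", "time_s", "status")), file,
              row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  d <- read.table(file, header = TRUE)
  data.frame(replica_id = d$replica_id, time = d$time_s, status = d$status)
}

#' Write a survival curve
#'
#' Columns \code{time_s S ci_low ci_high}.
#'
#' @param curve a [km_survival()] result.
#' @param file path.
#' @return the path, invisibly.
#' @export
write_survival <- function(curve, file) {
  write.table(setNames(as.data.frame(curve),
                       c("time_s", "S", "ci_low", "ci_high")),
              file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
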