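# CSV readers and writers for the two field-table schemas and for simulated
# trajectories.  Dialect: comma-separated, dot decimal, UTF-8, mandatory
# header.  Lengths are stored in metres; shoot orientation is stored in
# degrees from the horizontal (field convention) and converted to radians on
# read.

stop_row <- function(row, msg) stop(sprintf("row %d: %s", row, msg), call. = FALSE)

#' Read a morphology sample from CSV
#'
#' The internode table has one row per internode with columns `index`,
#' `length_m`, `diameter_m`, `leaf_count` and optionally `mass_kg`,
#' `leaf_mass_kg`. The shoot-level sidecar has a single row with columns
#' `reach_m`, `orientation_deg` and optionally bending columns `EI_Nm2`,
#' `d_v_m`, `d_h_m` (repeated rows allowed, one per bending position).
#'
#' @param internodes_path path to the internode CSV.
#' @param shoot_path optional path to the shoot-level CSV.
#' @return A [morphology_sample] (reach/orientation 0 when no sidecar given).
#' @export
read_morphology <- function(internodes_path, shoot_path = NULL) {
  tab <- utils::read.csv(internodes_path)
  req <- c("index", "length_m", "diameter_m", "leaf_count")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing column(s) in ", internodes_path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (cn in intersect(c(req, "mass_kg", "leaf_mass_kg"), names(tab))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[cn]]))))
    if (length(bad)) stop_row(bad[1], paste0("non-numeric value in '", cn, "'"))
  }
  bad <- which(tab$length_m <= 0)
  if (length(bad)) stop_row(bad[1], "non-positive internode length")
  bad <- which(diff(tab$index) <= 0)
  if (length(bad)) stop_row(bad[1] + 1L, "internode indices not strictly increasing")

  reach <- 0; orient <- 0; bending <- NULL
  if (!is.null(shoot_path)) {
    sh <- utils::read.csv(shoot_path)
    if (!all(c("reach_m", "orientation_deg") %in% names(sh)))
      stop("shoot sidecar must have columns reach_m, orientation_deg", call. = FALSE)
    reach <- sh$reach_m[1]
    orient <- sh$orientation_deg[1] * pi / 180
    if (all(c("EI_Nm2", "d_v_m", "d_h_m") %in% names(sh)))
      bending <- sh[, c("EI_Nm2", "d_v_m", "d_h_m")]
  }
  morphology_sample(tab, reach, orient, bending = bending)
}

#' Write a morphology sample to CSV
#'
#' @param sample a [morphology_sample].
#' @param internodes_path,shoot_path output paths (shoot sidecar skipped when
#'   `NULL`).
#' @return Invisibly, the sample.
#' @export
write_morphology <- function(sample, internodes_path, shoot_path = NULL) {
  utils::write.csv(sample$internodes, internodes_path, row.names = FALSE)
  if (!is.null(shoot_path)) {
    sh <- data.frame(reach_m = sample$reach_m,
                     orientation_deg = sample$orientation_rad * 180 / pi)
    if (!is.null(sample$bending)) sh <- cbind(sh, sample$bending)
    utils::write.csv(sh, shoot_path, row.names = FALSE)
  }
  invisible(sample)
}

#' Read extension series from a long-format CSV
#'
#' Columns: `shoot_id`, `date_day`, `internode_index`, `length_m`; one series
#' per shoot id.
#'
#' @param path CSV path.
#' @return A list of [extension_series].
#' @export
read_extension <- function(path) {
  tab <- utils::read.csv(path)
  req <- c("shoot_id", "date_day", "internode_index", "length_m")
  miss <- setdiff(req, names(tab))
  if (length(miss))
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- which(tab$length_m < 0)
  if (length(bad)) stop_row(bad[1], "negative internode length")
  lapply(split(tab, tab$shoot_id), function(d) {
    dates <- sort(unique(d$date_day))
    idx <- sort(unique(d$internode_index))
    m <- matrix(NA_real_, length(idx), length(dates))
    m[cbind(match(d$internode_index, idx), match(d$date_day, dates))] <- d$length_m
    if (anyNA(m))
      stop("incomplete internode x date grid for shoot ", d$shoot_id[1], call. = FALSE)
    extension_series(dates, m, shoot_id = as.character(d$shoot_id[1]))
  })
}

#' Write extension series to a long-format CSV
#'
#' @param series an [extension_series] or list of them.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_extension <- function(series, path) {
  if (inherits(series, "extension_series")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(es) {
    expand <- expand.grid(internode_index = seq_len(nrow(es$lengths)),
                          date_day = es$dates)
    data.frame(shoot_id = es$shoot_id, date_day = expand$date_day,
               internode_index = expand$internode_index,
               length_m = as.vector(es$lengths))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated trajectory to CSV
#'
#' One row per node and output frame, columns
#' `t, S, s, x, theta, kappa, px, py`; run metadata (model, parameters) in
#' `#`-prefixed header lines.
#'
#' @param trajectory a `shoot_trajectory` from [simulate_shoot()].
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(trajectory, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# morphorod trajectory: model=%s dt=%g g=%g theta0=%g",
                     trajectory$model, trajectory$dt, trajectory$g,
                     trajectory$theta0), con)
  writeLines(sprintf("# sensing: alpha=%g beta=%g gamma=%g delta=%g",
                     trajectory$sensing$alpha, trajectory$sensing$beta,
                     trajectory$sensing$gamma, trajectory$sensing$delta), con)
  long <- do.call(rbind, trajectory$frames)
  utils::write.csv(long, con, row.names = FALSE)
  invisible(path)
}
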