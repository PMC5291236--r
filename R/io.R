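# Plain-text I/O ----------------------------------------------------------------
#
# All on-disk formats are plain CSV with units embedded in column names, plus
# JSON sidecars for generation/analysis parameters. Readers validate the
# schema and report offending rows by line number (header = line 1).

read_csv_checked <- function(path, required_cols) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) abort_schema(sprintf("file is empty: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    abort_schema(sprintf("%s: missing column(s) %s", path,
                         paste(missing, collapse = ", ")))
  if (nrow(df) == 0L) abort_schema(sprintf("%s: no data rows", path))
  df
}

#' Write a sweep set as long-format CSV (+ JSON parameter sidecar)
#'
#' Columns: `experiment_id`, `sweep_id`, `holding_mV`, `time_ms`,
#' `current_pA`. If `params` is supplied it is written next to the CSV as
#' `<path>.json`.
#'
#' @param ss A `sweep_set`.
#' @param path Output CSV path.
#' @param params Optional list of generation parameters for the sidecar.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(ss, path, params = NULL) {
  stopifnot(inherits(ss, "sweep_set"))
  n_sw <- nrow(ss$currents); n_t <- ncol(ss$currents)
  df <- data.frame(
    experiment_id = ss$experiment_id,
    sweep_id = rep(ss$sweep_id, each = n_t),
    holding_mV = ss$holding_mV,
    time_ms = rep(ss$time_ms, times = n_sw),
    current_pA = as.vector(t(ss$currents))
  )
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read a long-format sweep CSV into a sweep set
#'
#' @param path CSV path (dialect of [write_sweep_csv()]).
#' @return A `sweep_set`.
#' @export
read_sweep_csv <- function(path) {
  df <- read_csv_checked(path, c("experiment_id", "sweep_id", "holding_mV",
                                 "time_ms", "current_pA"))
  bad <- which(!is.finite(df$time_ms) | !is.finite(df$current_pA))
  if (length(bad))
    abort_schema(sprintf("%s: non-numeric sample at line %d", path, bad[1] + 1L))
  ids <- unique(df$sweep_id)
  times <- df$time_ms[df$sweep_id == ids[1]]
  per <- split(df$current_pA, factor(df$sweep_id, levels = ids))
  len <- vapply(per, length, integer(1))
  if (any(len != length(times))) {
    off <- names(len)[len != length(times)][1]
    abort_schema(sprintf("%s: sweep '%s' has %d samples, expected %d",
                         path, off, len[[off]], length(times)))
  }
  structure(list(
    time_ms = times,
    currents = do.call(rbind, per),
    holding_mV = as.numeric(df$holding_mV[1]),
    dt_ms = stats::median(diff(times)),
    experiment_id = df$experiment_id[1],
    animal_id = if ("animal_id" %in% names(df)) df$animal_id[1] else NA_character_,
    sweep_id = ids,
    series_resistance_MOhm = NULL,
    truth = NULL
  ), class = "sweep_set")
}

#' Write / read paired-trial outcome CSVs
#'
#' Columns: `trial`, `cell_a_success`, `cell_b_success` (0/1).
#'
#' @param outcomes A `trial_outcomes` object.
#' @param path CSV path.
#' @return `path` / a `trial_outcomes` object.
#' @export
write_trials_csv <- function(outcomes, path) {
  stopifnot(inherits(outcomes, "trial_outcomes"))
  utils::write.csv(data.frame(
    trial = seq_along(outcomes$success_a),
    cell_a_success = as.integer(outcomes$success_a),
    cell_b_success = as.integer(outcomes$success_b)
  ), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- read_csv_checked(path, c("trial", "cell_a_success", "cell_b_success"))
  for (col in c("cell_a_success", "cell_b_success")) {
    bad <- which(!df[[col]] %in% c(0L, 1L))
    if (length(bad))
      abort_schema(sprintf("%s: %s must be 0/1; offending line %d",
                           path, col, bad[1] + 1L))
  }
  trial_outcomes(df$cell_a_success == 1L, df$cell_b_success == 1L,
                 experiment_id = basename(path))
}

#' Write / read nuclei point CSVs
#'
#' Columns: `section`, `x_um`, `y_um`.
#'
#' @param field A `point_field`.
#' @param path CSV path.
#' @param section_spacing_um Section spacing used when reading (um).
#' @return `path` / a `point_field`.
#' @export
write_points_csv <- function(field, path) {
  stopifnot(inherits(field, "point_field"))
  utils::write.csv(field$points, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_points_csv
#' @export
read_points_csv <- function(path, section_spacing_um = 3) {
  df <- read_csv_checked(path, c("section", "x_um", "y_um"))
  bad <- which(!is.finite(df$x_um) | !is.finite(df$y_um))
  if (length(bad))
    abort_schema(sprintf("%s: non-finite coordinate at line %d", path, bad[1] + 1L))
  point_field(df, section_spacing_um = section_spacing_um)
}

#' Write / read axon segment CSVs
#'
#' Columns: `x1_um`, `y1_um`, `x2_um`, `y2_um` and optionally `compartment`.
#'
#' @param segments Segment data frame.
#' @param path CSV path.
#' @return `path` / a segment data frame.
#' @export
write_segments_csv <- function(segments, path) {
  utils::write.csv(segments, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  df <- read_csv_checked(path, c("x1_um", "y1_um", "x2_um", "y2_um"))
  for (col in c("x1_um", "y1_um", "x2_um", "y2_um")) {
    bad <- which(!is.finite(df[[col]]))
    if (length(bad))
      abort_schema(sprintf("%s: non-finite %s at line %d", path, col, bad[1] + 1L))
  }
  df
}
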