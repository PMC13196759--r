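# Readers and writers for the pipeline's plain-text interchange formats
# (CSV with header, UTF-8, "." decimal) and NIfTI volumes.

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  check_that(length(missing) == 0,
             paste0(what, " is missing required columns: ",
                    paste(missing, collapse = ", ")))
  invisible(df)
}

#' Read larva tracking tables
#'
#' Reads a tracking CSV (`well_id`, `time_s`, `x_mm`, `y_mm`). Rows with
#' missing or non-finite coordinates are rejected with a warning naming
#' their line numbers; per-well frame spacing is validated downstream by
#' [bin_activity()].
#'
#' @param path CSV file path.
#' @return Long tibble of tracks.
#' @export
read_tracks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("well_id", "time_s", "x_mm", "y_mm"), "tracking file")
  check_that(nrow(df) > 0, paste0("empty tracking file: ", path))
  ok <- is.finite(df$time_s) & is.finite(df$x_mm) & is.finite(df$y_mm)
  if (any(!ok)) {
    warn(paste0("read_tracks: rejected ", sum(!ok), " malformed row(s) at line(s) ",
                paste(utils::head(which(!ok) + 1, 20), collapse = ", ")))
    df <- df[ok, ]
  }
  check_that(nrow(df) > 0, "no valid rows after removing malformed ones")
  as_tibble(df[, c("well_id", "time_s", "x_mm", "y_mm")])
}

#' Write tracks to CSV
#' @param tracks Long track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  require_columns(tracks, c("well_id", "time_s", "x_mm", "y_mm"), "tracks")
  readr::write_csv(tracks[, c("well_id", "time_s", "x_mm", "y_mm")], path)
  invisible(path)
}

#' Read/write a light schedule as CSV
#'
#' Schedules are stored as plain interval tables (`state`, `start_s`,
#' `end_s`) with the acclimation length recoverable from the first
#' off-interval boundary.
#'
#' @param path File path.
#' @param acclimation_s Acclimation length to re-attach on read.
#' @return A `photokin_schedule` (read) or `path` (write).
#' @export
read_schedule <- function(path, acclimation_s = 0) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("state", "start_s", "end_s"), "schedule file")
  as_schedule(df, acclimation_s = acclimation_s)
}

#' @rdname read_schedule
#' @param schedule Schedule to write.
#' @export
write_schedule <- function(schedule, path) {
  validate_schedule(schedule)
  readr::write_csv(as_tibble(schedule)[, c("state", "start_s", "end_s")], path)
  invisible(path)
}

#' Read/write photokinesis index tables
#' @param path File path.
#' @return A `pi_table` tibble (read) or `path` (write).
#' @export
read_pi_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("well_id", "delta_on_off", "delta_off_on", "pi",
                        "valid", "reason", "population"), "PI table")
  out <- as_tibble(df)
  class(out) <- c("pi_table", class(tibble()))
  out
}

#' @rdname read_pi_table
#' @param pi_table Table to write.
#' @export
write_pi_table <- function(pi_table, path) {
  require_columns(pi_table, c("well_id", "delta_on_off", "delta_off_on",
                              "pi", "valid", "reason", "population"),
                  "PI table")
  readr::write_csv(as_tibble(pi_table), path)
  invisible(path)
}

#' Read/write region volume tables
#' @param path File path.
#' @return Long tibble `fish_id`, `region`, `volume_um3` (read) or `path`.
#' @export
read_region_volumes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("fish_id", "region", "volume_um3"), "volume table")
  as_tibble(df)
}

#' @rdname read_region_volumes
#' @param volumes Table to write.
#' @export
write_region_volumes <- function(volumes, path) {
  require_columns(volumes, c("fish_id", "region", "volume_um3"), "volume table")
  readr::write_csv(as_tibble(volumes), path)
  invisible(path)
}

#' Read/write neuron trace tables
#' @param path File path.
#' @return Long tibble `neuron_id`, `time_s`, `fluorescence` (read) or
#'   `path`.
#' @export
read_traces <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(df, c("neuron_id", "time_s", "fluorescence"), "trace table")
  as_tibble(df)
}

#' @rdname read_traces
#' @param traces Table to write.
#' @export
write_traces <- function(traces, path) {
  require_columns(traces, c("neuron_id", "time_s", "fluorescence"),
                  "trace table")
  readr::write_csv(as_tibble(traces), path)
  invisible(path)
}

#' Read/write 3D volumes as NIfTI
#'
#' Thin wrappers over RNifti keeping the isotropic voxel size in the
#' header.
#'
#' @param path NIfTI file path (`.nii` or `.nii.gz`).
#' @return A plain 3D array with a `voxel_size` attribute (read) or
#'   `path` (write).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.vector(img), dim(img))
  attr(out, "voxel_size") <- RNifti::pixdim(img)[1]
  out
}

#' @rdname read_volume
#' @param vol 3D array.
#' @param voxel_size Isotropic voxel size, um.
#' @export
write_volume <- function(vol, path, voxel_size = 2) {
  check_that(length(dim(vol)) == 3, "`vol` must be a 3D array")
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- rep(voxel_size, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
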