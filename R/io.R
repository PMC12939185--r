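# Plain-text array containers with JSON sidecars. Layout mirrors an HDF5
# hierarchy ("rf/samples" + "rf/meta", "map/values" + "map/meta") using a
# whitespace-delimited matrix file next to a JSON metadata file, so frames
# and maps survive version control and text-only pipelines.

write_matrix_txt <- function(m, path) {
  utils::write.table(format(m, digits = 10, scientific = TRUE, trim = TRUE),
                     path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
}

read_matrix_txt <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE,
                                   colClasses = "numeric"))
  dimnames(m) <- NULL
  m
}

#' Write / read an RF frame container
#'
#' Stores the 2-D sample array as a whitespace-delimited text matrix at
#' `<path>.txt` and the acquisition metadata as `<path>.json` with the
#' layout `{"rf": {"samples": "<file>", "meta": {...}}}`.
#'
#' @param frame An [rf_frame()].
#' @param path Base path (without extension).
#' @return `write_rf_frame`: the base path, invisibly. `read_rf_frame`: the
#'   reconstructed [rf_frame()].
#' @export
write_rf_frame <- function(frame, path) {
  if (!inherits(frame, "rf_frame")) stop("`frame` must be an rf_frame", call. = FALSE)
  write_matrix_txt(frame$samples, paste0(path, ".txt"))
  meta <- list(rf = list(
    samples = basename(paste0(path, ".txt")),
    meta = frame[c("fs", "f0", "pulse_length", "lateral_pitch", "sound_speed")]))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rf_frame
#' @export
read_rf_frame <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  samples <- read_matrix_txt(file.path(dirname(path), meta$rf$samples))
  dimnames(samples) <- NULL
  m <- meta$rf$meta
  rf_frame(samples, fs = m$fs, f0 = m$f0, pulse_length = m$pulse_length,
           lateral_pitch = m$lateral_pitch, sound_speed = m$sound_speed)
}

#' Write / read a parametric map container
#'
#' Same text-plus-JSON layout as [write_rf_frame()], with keys
#' `{"map": {"values": "<file>", "meta": {...}}}` carrying the parameter id,
#' window geometry and grid origin.
#'
#' @param map A `parametric_map`.
#' @param path Base path (without extension).
#' @return `write_parametric_map`: the base path, invisibly;
#'   `read_parametric_map`: the reconstructed map.
#' @export
write_parametric_map <- function(map, path) {
  if (!inherits(map, "parametric_map")) stop("`map` must be a parametric_map", call. = FALSE)
  write_matrix_txt(map$values, paste0(path, ".txt"))
  meta <- list(map = list(
    values = basename(paste0(path, ".txt")),
    meta = list(parameter_id = map$parameter_id,
                window = unclass(map$window),
                origin = map$origin)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_parametric_map
#' @export
read_parametric_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  values <- read_matrix_txt(file.path(dirname(path), meta$map$values))
  dimnames(values) <- NULL
  w <- meta$map$meta$window
  win <- window_spec(w$side_axial, w$side_lateral, w$step_axial, w$step_lateral)
  win$multiplier <- w$multiplier
  new_parametric_map(values, meta$map$meta$parameter_id, win,
                     origin = as.numeric(meta$map$meta$origin))
}

#' Write / read a feature table as CSV
#'
#' Standard comma-separated layout with a header row: `subject_id`, `label`,
#' then the feature columns.
#'
#' @param table A `feature_table`.
#' @param path CSV file path.
#' @return `write_feature_table`: `path`, invisibly; `read_feature_table`:
#'   the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Serialize a simulated cohort to a directory
#'
#' Writes one RF frame container and one ROI mask (0/1 text matrix) per
#' subject plus the ground-truth table `truth.csv`.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- cohort$truth$subject_id
  for (i in seq_along(cohort$frames)) {
    write_rf_frame(cohort$frames[[i]], file.path(dir, ids[i]))
    write_matrix_txt(cohort$masks[[i]] * 1L,
                     file.path(dir, paste0(ids[i], "_mask.txt")))
  }
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
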