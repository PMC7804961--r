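#' Read / write long-format cohort tables
#'
#' The on-disk interchange format is a long CSV with columns
#' \code{subject_id, puberty, sex, session, block, trial, parameter, value}.
#' \code{read_cohort_table} accepts arbitrary CSV exports through a column
#' mapping (\code{list(subject_id = "Subject", ...)}) that renames the file's
#' columns onto this schema before validation.
#'
#' @param table A \code{cohort_table} data.frame.
#' @param path CSV file path.
#' @param mapping Optional named list: names are the schema columns, values
#'   the corresponding column names in the file.
#' @return \code{read_cohort_table} returns a \code{cohort_table};
#'   \code{write_cohort_table} returns \code{path} invisibly.
#' @export
write_cohort_table <- function(table, path) {
  cols <- c("subject_id", "puberty", "sex", "session", "block", "trial",
            "parameter", "value")
  for (c in setdiff(cols, names(table))) table[[c]] <- NA
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (schema_col in names(mapping)) {
      src <- mapping[[schema_col]]
      if (!src %in% names(df))
        stop(sprintf("mapping: column '%s' (for '%s') not found in %s",
                     src, schema_col, path), call. = FALSE)
      names(df)[names(df) == src] <- schema_col
    }
  }
  check_columns(df, c("subject_id", "puberty", "session", "trial",
                      "parameter", "value"), basename(path))
  if (!"block" %in% names(df)) df$block <- NA_integer_
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read one trial recording (CSV + JSON sidecar)
#'
#' Marker positions go to \code{<stem>.csv} (columns \code{t},
#' \code{wrist_x/y/z}, \code{thumb_x/y/z}, \code{index_x/y/z}); the sidecar
#' \code{<stem>.json} holds identification, switch release time, sampling
#' rate and (for synthetic trials) the embedded ground-truth parameters.
#'
#' @param recording A \code{trial_recording}.
#' @param dir Output directory (created if needed).
#' @param stem File stem; default built from subject/session/block/trial.
#' @return The CSV path invisibly.
#' @export
write_trial_recording <- function(recording, dir, stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stem <- stem %||% sprintf("trial_%s_%s_b%s_%03d",
                            recording$subject_id,
                            recording$session %||% "NA",
                            recording$block %||% "NA",
                            recording$trial_index)
  df <- data.frame(t = recording$sample_times,
                   wrist_x = recording$wrist_xyz[, 1],
                   wrist_y = recording$wrist_xyz[, 2],
                   wrist_z = recording$wrist_xyz[, 3],
                   thumb_x = recording$thumb_xyz[, 1],
                   thumb_y = recording$thumb_xyz[, 2],
                   thumb_z = recording$thumb_xyz[, 3],
                   index_x = recording$index_xyz[, 1],
                   index_y = recording$index_xyz[, 2],
                   index_z = recording$index_xyz[, 3])
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(df, csv, row.names = FALSE)
  meta <- list(subject_id = recording$subject_id,
               session = recording$session,
               block = recording$block,
               trial_index = recording$trial_index,
               fs = recording$fs,
               switch_release_time = recording$switch_release_time,
               ground_truth = recording$ground_truth)
  jsonlite::write_json(meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(csv)
}

#' @rdname write_trial_recording
#' @param csv_path Path to the trial CSV; the sidecar is looked up next to it.
#' @export
read_trial_recording <- function(csv_path) {
  df <- utils::read.csv(csv_path)
  json_path <- sub("\\.csv$", ".json", csv_path)
  meta <- if (file.exists(json_path)) jsonlite::read_json(json_path,
                                                          simplifyVector = TRUE)
          else list()
  structure(list(
    subject_id = meta$subject_id %||% NA_character_,
    session = meta$session %||% NA_character_,
    block = meta$block %||% NA_integer_,
    trial_index = meta$trial_index %||% NA_integer_,
    sample_times = df$t,
    fs = meta$fs %||% 1 / stats::median(diff(df$t)),
    wrist_xyz = as.matrix(df[, c("wrist_x", "wrist_y", "wrist_z")]),
    thumb_xyz = as.matrix(df[, c("thumb_x", "thumb_y", "thumb_z")]),
    index_xyz = as.matrix(df[, c("index_x", "index_y", "index_z")]),
    switch_release_time = meta$switch_release_time %||% df$t[1],
    ground_truth = meta$ground_truth
  ), class = "trial_recording")
}

#' @rdname write_trial_recording
#' @param dir Directory containing trial CSV/JSON pairs.
#' @export
read_trials_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no trial CSVs found in %s", dir), call. = FALSE)
  lapply(files, read_trial_recording)
}
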