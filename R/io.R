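#' Write a recording to the on-disk session format
#'
#' Recordings are stored as one CSV per subject per processing stage
#' (`<subject>_<stage>.csv`, a `time_s` column plus one column per channel in
#' canonical order) with a JSON sidecar (`<subject>_<stage>.json`) declaring
#' `subject_id`, `fs` and `stage`. The flat-file layout keeps sessions
#' inspectable with any spreadsheet or command-line tool.
#'
#' @param rec An [emg_recording()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path of the written CSV.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "emg_recording"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, paste0(rec$subject_id, "_", rec$stage))
  readr::write_csv(rec$signals, paste0(base, ".csv"))
  jsonlite::write_json(
    list(subject_id = rec$subject_id, fs = rec$fs, stage = rec$stage),
    paste0(base, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(paste0(base, ".csv"))
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the signal CSV; the JSON sidecar is expected next to
#'   it with the same basename.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "faceemg_format_error")
  }
  sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar)) {
    rlang::abort(paste0("Missing JSON sidecar: ", sidecar), class = "faceemg_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("subject_id", "fs")) {
    if (is.null(meta[[field]])) {
      rlang::abort(paste0("Sidecar lacks required field '", field, "'."),
                   class = "faceemg_format_error")
    }
  }
  sig <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("time_s", emg_channels()), names(sig))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Signal CSV is missing column(s): ", paste(missing, collapse = ", ")),
      class = "faceemg_format_error"
    )
  }
  emg_recording(sig, fs = as.numeric(meta$fs), subject_id = meta$subject_id,
                stage = if (is.null(meta$stage)) "raw" else meta$stage)
}

#' Read and write per-video self-report ratings
#'
#' Ratings CSVs hold one row per (subject, video) with integer valence and
#' arousal on the 1-9 scale (1 = very unpleasant / very low arousal, 5 =
#' neutral / medium, 9 = very pleasant / very high arousal).
#'
#' @param path CSV path with columns `subject_id`, `video_id`, `valence`,
#'   `arousal`.
#' @return A tibble of validated rating records.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "faceemg_format_error")
  }
  ratings <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_ratings(ratings)
}

#' @rdname read_ratings
#' @param ratings A data frame of rating records.
#' @export
write_ratings <- function(ratings, path) {
  ratings <- validate_ratings(ratings)
  readr::write_csv(ratings, path)
  invisible(path)
}

#' Validate a table of rating records
#'
#' @inheritParams write_ratings
#' @return The validated ratings as a tibble (invisible errors otherwise).
#' @export
validate_ratings <- function(ratings) {
  needed <- c("subject_id", "video_id", "valence", "arousal")
  missing <- setdiff(needed, names(ratings))
  if (length(missing) > 0) {
    rlang::abort(paste0("Ratings table lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "faceemg_format_error")
  }
  for (scale in c("valence", "arousal")) {
    v <- ratings[[scale]]
    bad <- which(!is.finite(v) | v < 1 | v > 9 | v != round(v))
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("%s out of 1-9 range (or non-integer) in row(s): %s",
                scale, paste(utils::head(bad, 5), collapse = ", ")),
        class = "faceemg_validation_error"
      )
    }
  }
  dup <- duplicated(ratings[c("subject_id", "video_id")])
  if (any(dup)) {
    rlang::abort(
      paste0("Duplicate (subject_id, video_id) pair(s) in row(s): ",
             paste(utils::head(which(dup), 5), collapse = ", ")),
      class = "faceemg_validation_error"
    )
  }
  dplyr::mutate(tibble::as_tibble(ratings),
                valence = as.integer(.data$valence),
                arousal = as.integer(.data$arousal))
}

#' Read and write session video schedules
#'
#' A schedule is one row per video event with its predefined category and
#' half-open presentation interval `[start_s, end_s)` in seconds from session
#' start.
#'
#' @param path CSV path with columns `subject_id`, `video_id`, `category`,
#'   `start_s`, `end_s`.
#' @return A tibble of validated, time-ordered events.
#' @export
read_schedule <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("No such file: ", path), class = "faceemg_format_error")
  }
  sched <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_schedule(sched)
}

#' @rdname read_schedule
#' @param schedule A data frame of video events.
#' @export
write_schedule <- function(schedule, path) {
  schedule <- validate_schedule(schedule)
  readr::write_csv(schedule, path)
  invisible(path)
}

#' Validate a schedule table
#' @inheritParams write_schedule
#' @return The validated schedule as a tibble ordered by `start_s`.
#' @export
validate_schedule <- function(schedule) {
  needed <- c("subject_id", "video_id", "category", "start_s", "end_s")
  missing <- setdiff(needed, names(schedule))
  if (length(missing) > 0) {
    rlang::abort(paste0("Schedule lacks column(s): ",
                        paste(missing, collapse = ", ")),
                 class = "faceemg_format_error")
  }
  bad_cat <- setdiff(unique(schedule$category), video_categories())
  if (length(bad_cat) > 0) {
    rlang::abort(paste0("Unknown video category: ",
                        paste(bad_cat, collapse = ", ")),
                 class = "faceemg_validation_error")
  }
  if (any(schedule$end_s <= schedule$start_s)) {
    rlang::abort("Every event must satisfy end_s > start_s.",
                 class = "faceemg_validation_error")
  }
  schedule <- dplyr::arrange(tibble::as_tibble(schedule), .data$start_s)
  if (nrow(schedule) > 1) {
    overlap <- schedule$start_s[-1] < schedule$end_s[-nrow(schedule)]
    if (any(overlap)) {
      rlang::abort("Schedule events overlap.", class = "faceemg_validation_error")
    }
  }
  schedule
}

#' Video stimulus categories
#' @return Character vector `c("neutral", "negative", "positive")`.
#' @export
video_categories <- function() c("neutral", "negative", "positive")

# Category multiset of a study-conformant 25-video session.
study_category_counts <- function() {
  c(neutral = 10L, negative = 6L, positive = 9L)
}

#' Validate a session before analysis
#'
#' Report-only consistency check of a recording against its schedule and
#' ratings: events must fall inside the recorded span, every video needs a
#' rating, and a study-conformant session presents 25 videos with the
#' category multiset 10 neutral / 6 negative / 9 positive.
#'
#' @param recording An [emg_recording()].
#' @param schedule Schedule tibble (see [read_schedule()]).
#' @param ratings Ratings tibble (see [read_ratings()]).
#' @return A tibble with columns `violation` and `detail`; zero rows means
#'   the session is conformant.
#' @export
validate_session <- function(recording, schedule, ratings) {
  stopifnot(inherits(recording, "emg_recording"))
  schedule <- validate_schedule(schedule)
  ratings <- validate_ratings(ratings)
  out <- list()
  dur <- recording_duration(recording)

  late <- schedule$video_id[schedule$end_s > dur + 1e-9]
  for (v in late) {
    out[[length(out) + 1L]] <- c("event_out_of_range",
                                 sprintf("video %s ends after recording end (%.1f s)", v, dur))
  }

  unrated <- setdiff(schedule$video_id,
                     ratings$video_id[ratings$subject_id == recording$subject_id])
  for (v in unrated) {
    out[[length(out) + 1L]] <- c("missing_rating", sprintf("video %s has no rating", v))
  }

  counts <- table(factor(schedule$category, levels = video_categories()))
  want <- study_category_counts()
  for (cat in names(want)) {
    if (counts[[cat]] != want[[cat]]) {
      out[[length(out) + 1L]] <- c(
        "category_count",
        sprintf("category %s: %d video(s), expected %d", cat, counts[[cat]], want[[cat]])
      )
    }
  }

  if (length(out) == 0) {
    return(tibble::tibble(violation = character(), detail = character()))
  }
  tibble::tibble(
    violation = vapply(out, `[`, "", 1L),
    detail = vapply(out, `[`, "", 2L)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Convenience reader turning a YAML file into a [cohort_config()]; any field
#' not present keeps its default.
#'
#' @param path Path to a YAML file whose keys match [cohort_config()]
#'   arguments.
#' @return A `cohort_config` object.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  vals <- vals[intersect(names(vals), known)]
  if (!is.null(vals$emg_band)) vals$emg_band <- as.numeric(vals$emg_band)
  do.call(cohort_config, vals)
}
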