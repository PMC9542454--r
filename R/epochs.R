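#' Mean normalized amplitude per video
#'
#' Averages each channel's normalized envelope over every video event.
#' An envelope sample belongs to a video when its window *start* time lies in
#' the half-open interval `[start_s, end_s)`; with the default 10 s rating
#' breaks a window can never straddle two videos.
#'
#' @param env Long normalized envelope tibble (see [session_envelopes()]).
#' @param schedule Schedule tibble for the same subject(s).
#' @return Tibble `subject_id`, `video_id`, `category`, `channel`,
#'   `mean_amp`.
#' @export
per_video_amplitude <- function(env, schedule) {
  stopifnot(is.data.frame(env),
            all(c("subject_id", "channel", "time_s", "amplitude") %in% names(env)))
  schedule <- validate_schedule(schedule)
  span <- max(env$time_s)
  hop <- min(diff(sort(unique(env$time_s))), Inf)
  late <- schedule$video_id[schedule$end_s > span + hop + 1e-9]
  if (length(late) > 0) {
    rlang::abort(paste0("Event(s) extend beyond the envelope span: ",
                        paste(late, collapse = ", ")),
                 class = "faceemg_validation_error")
  }
  # single-pass interval assignment: each envelope sample to the event whose
  # half-open [start_s, end_s) contains its window start, per subject
  purrr::map_dfr(split(env, env$subject_id), function(env_s) {
    sched_s <- schedule[schedule$subject_id == env_s$subject_id[1], ]
    if (nrow(sched_s) == 0) return(NULL)
    idx <- findInterval(env_s$time_s, sched_s$start_s)
    inside <- idx > 0 & env_s$time_s < sched_s$end_s[pmax(idx, 1)]
    env_s |>
      dplyr::mutate(video_id = ifelse(inside, sched_s$video_id[pmax(idx, 1)], NA)) |>
      dplyr::filter(!is.na(.data$video_id)) |>
      dplyr::group_by(.data$subject_id, .data$video_id, .data$channel) |>
      dplyr::summarise(mean_amp = mean(.data$amplitude), .groups = "drop")
  }) |>
    dplyr::left_join(dplyr::distinct(schedule, .data$video_id, .data$category),
                     by = "video_id") |>
    dplyr::select("subject_id", "video_id", "category", "channel", "mean_amp") |>
    dplyr::arrange(.data$subject_id, .data$video_id, .data$channel)
}

#' Bin a self-report rating into the analysis conditions
#'
#' Ratings 1-4 map to the negative-valence / low-arousal bin, 6-9 to the
#' positive-valence / high-arousal bin; the scale midpoint 5 is excluded
#' (`NA`).
#'
#' @param rating Integer vector of ratings on the 1-9 scale.
#' @param kind `"valence"` or `"arousal"`.
#' @return Character vector: `"V_negative"`/`"V_positive"` or
#'   `"A_low"`/`"A_high"`, with `NA` for midpoint ratings.
#' @export
#' @examples
#' bin_rating(c(1, 4, 5, 6, 9), "valence")
bin_rating <- function(rating, kind = c("valence", "arousal")) {
  kind <- match.arg(kind)
  if (any(!is.finite(rating) | rating < 1 | rating > 9)) {
    rlang::abort("Ratings must lie in 1-9.", class = "faceemg_validation_error")
  }
  low <- if (kind == "valence") "V_negative" else "A_low"
  high <- if (kind == "valence") "V_positive" else "A_high"
  dplyr::case_when(rating <= 4 ~ low, rating >= 6 ~ high, TRUE ~ NA_character_)
}

condition_schemes <- function() {
  c("valence_bin", "arousal_bin", "video_type", "valence_level", "arousal_level")
}

#' Per-subject condition means
#'
#' Aggregates per-video mean amplitudes into the per-subject condition means
#' that feed the group statistics: the unweighted mean, over the subject's
#' videos falling in a condition, of the per-video mean normalized amplitude.
#' Conditions are defined by the `scheme`:
#' \describe{
#'   \item{`valence_bin`}{subjective valence 1-4 vs 6-9 (`V_negative`,
#'     `V_positive`; midpoint excluded).}
#'   \item{`arousal_bin`}{subjective arousal 1-4 vs 6-9 (`A_low`, `A_high`).}
#'   \item{`video_type`}{the predefined stimulus category (`W_negative`,
#'     `W_neutral`, `W_positive`).}
#'   \item{`valence_level`, `arousal_level`}{one condition per rating level
#'     1-9.}
#' }
#' Subjects with no video in a condition contribute no record for it; they
#' are reported via the `dropped` attribute and handled pairwise downstream.
#'
#' @param per_video Output of [per_video_amplitude()].
#' @param ratings Ratings tibble (required for rating-based schemes).
#' @param scheme One of [condition_schemes()].
#' @return Tibble `subject_id`, `channel`, `scheme`, `condition`, `value`,
#'   `n_videos`, with attribute `dropped` naming subject/condition pairs that
#'   have no videos.
#' @export
condition_means <- function(per_video, ratings = NULL,
                            scheme = c("valence_bin", "arousal_bin",
                                       "video_type", "valence_level",
                                       "arousal_level")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(per_video),
            all(c("subject_id", "video_id", "channel", "mean_amp") %in% names(per_video)))

  if (scheme == "video_type") {
    if (!"category" %in% names(per_video)) {
      rlang::abort("`per_video` needs a `category` column for scheme = 'video_type'.",
                   class = "faceemg_validation_error")
    }
    dat <- dplyr::mutate(per_video, condition = paste0("W_", .data$category))
    levels_all <- paste0("W_", video_categories())
  } else {
    if (is.null(ratings)) {
      rlang::abort("`ratings` are required for rating-based schemes.",
                   class = "faceemg_validation_error")
    }
    ratings <- validate_ratings(ratings)
    dat <- dplyr::inner_join(per_video, ratings, by = c("subject_id", "video_id"))
    if (nrow(dat) < nrow(per_video)) {
      rlang::abort("Some videos lack ratings; cannot aggregate a rating-based scheme.",
                   class = "faceemg_validation_error")
    }
    kind <- if (grepl("^valence", scheme)) "valence" else "arousal"
    if (endsWith(scheme, "_bin")) {
      dat <- dplyr::mutate(dat, condition = bin_rating(.data[[kind]], kind))
      levels_all <- if (kind == "valence") c("V_negative", "V_positive") else c("A_low", "A_high")
    } else {
      dat <- dplyr::mutate(dat, condition = as.character(.data[[kind]]))
      levels_all <- as.character(1:9)
    }
    dat <- dplyr::filter(dat, !is.na(.data$condition))
  }

  out <- dat |>
    dplyr::group_by(.data$subject_id, .data$channel, .data$condition) |>
    dplyr::summarise(value = mean(.data$mean_amp),
                     n_videos = dplyr::n_distinct(.data$video_id),
                     .groups = "drop") |>
    dplyr::mutate(scheme = scheme) |>
    dplyr::select("subject_id", "channel", "scheme", "condition", "value",
                  "n_videos") |>
    dplyr::arrange(.data$subject_id, .data$channel, .data$condition)

  if (endsWith(scheme, "_bin") || scheme == "video_type") {
    full <- tidyr::expand_grid(subject_id = unique(per_video$subject_id),
                               condition = levels_all)
    present <- dplyr::distinct(out, .data$subject_id, .data$condition)
    dropped <- dplyr::anti_join(full, present, by = c("subject_id", "condition"))
    if (nrow(dropped) > 0) {
      rlang::inform(paste0(
        nrow(dropped), " subject/condition cell(s) have no videos under scheme '",
        scheme, "'; affected subjects are dropped pairwise from paired tests."
      ), class = "faceemg_missing_condition")
    }
    attr(out, "dropped") <- dropped
  }
  out
}
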