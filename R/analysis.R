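#' Per-video amplitudes for one session
#'
#' Convenience wrapper running one raw recording through denoising, the
#' envelope pipeline and per-video aggregation.
#'
#' @param recording A raw [emg_recording()].
#' @param schedule The subject's schedule tibble.
#' @param denoise_first Run [denoise()] before envelope extraction (default
#'   `TRUE`; set `FALSE` only for signals known to be clean, e.g. null
#'   simulations without interference).
#' @inheritParams session_envelopes
#' @return Per-video amplitude tibble (see [per_video_amplitude()]).
#' @export
analyze_session <- function(recording, schedule, denoise_first = TRUE,
                            method = "rms", window_s = 0.25, hop_s = 0.05,
                            lo_pct = 5, hi_pct = 95) {
  rec <- if (denoise_first) denoise(recording) else recording
  env <- session_envelopes(rec, method = method, window_s = window_s,
                           hop_s = hop_s, lo_pct = lo_pct, hi_pct = hi_pct)
  per_video_amplitude(env, schedule)
}

#' Group analysis of per-video amplitudes and ratings
#'
#' The statistical surface of the pipeline, starting from per-video mean
#' amplitudes: the manipulation check on the self-reports, the per-subject
#' condition means under the three aggregation schemes, the Bonferroni-
#' corrected paired Wilcoxon families (m = 6 for each rating-bin scheme,
#' m = 18 for video type), the per-subject-per-level valence means with
#' segmented Pearson correlations (levels 1-5, 5-9, 1-9) and the quadratic
#' amplitude-versus-valence trend per modality.
#'
#' @param per_video Per-video amplitudes for all subjects (six channels:
#'   five sensors plus `"sensors_average"`).
#' @param ratings Ratings tibble for all subjects.
#' @param schedule Schedule tibble (category map).
#' @return An object of class `faceemg_analysis`; see Details.
#' @details The returned list has elements `manipulation`, `condition_means`
#'   (named list per scheme), `paired` (one tibble of all three families),
#'   `level_means` (per-subject per-valence-level means), `segment_cors`
#'   (tibble channel x segment), `trends` (named list of [quadratic_trend()]
#'   fits) and `trend_coefficients` (tibble).
#' @export
analyze_cohort_amplitudes <- function(per_video, ratings, schedule) {
  ratings <- validate_ratings(ratings)

  manip <- manipulation_check(ratings, schedule)

  schemes <- c("valence_bin", "arousal_bin", "video_type")
  cmeans <- lapply(schemes, function(sc) {
    rlang::with_options(
      condition_means(per_video, ratings, scheme = sc),
      rlib_message_verbosity = "quiet"
    )
  })
  names(cmeans) <- schemes

  paired <- dplyr::bind_rows(lapply(schemes, function(sc) {
    paired_amplitude_analysis(cmeans[[sc]], scheme = sc)
  }))

  level_means <- rlang::with_options(
    condition_means(per_video, ratings, scheme = "valence_level"),
    rlib_message_verbosity = "quiet"
  ) |>
    dplyr::mutate(level = as.numeric(.data$condition))

  segments <- list(c(1, 5), c(5, 9), c(1, 9))
  seg_rows <- list()
  trends <- list()
  for (ch in intersect(analysis_channels(), unique(level_means$channel))) {
    lm_ch <- dplyr::filter(level_means, .data$channel == ch)
    for (seg in segments) {
      row <- tryCatch(
        segment_pearson(lm_ch$level, lm_ch$value, seg[1], seg[2]),
        faceemg_validation_error = function(e) {
          tibble::tibble(lo = seg[1], hi = seg[2], r = NA_real_, p = NA_real_,
                         n = NA_integer_)
        }
      )
      seg_rows[[length(seg_rows) + 1L]] <- dplyr::mutate(
        row, channel = ch,
        segment = sprintf("[%d-%d]", seg[1], seg[2]),
        annotation = p_stars(.data$p), .before = 1
      )
    }
    trends[[ch]] <- quadratic_trend(lm_ch$level, lm_ch$value)
  }

  trend_coef <- purrr::imap_dfr(trends, function(tr, ch) {
    tibble::tibble(channel = ch,
                   intercept = tr$coefficients["intercept"],
                   linear = tr$coefficients["linear"],
                   quadratic = tr$coefficients["quadratic"],
                   n = tr$n)
  })

  structure(
    list(manipulation = manip, condition_means = cmeans, paired = paired,
         level_means = level_means, segment_cors = dplyr::bind_rows(seg_rows),
         trends = trends, trend_coefficients = trend_coef),
    class = "faceemg_analysis"
  )
}

#' Full cohort analysis
#'
#' Runs the complete pipeline for a cohort: for each subject, denoising,
#' envelope extraction with winsorized per-subject normalization, per-video
#' aggregation; then the group statistics of [analyze_cohort_amplitudes()].
#' When given a [cohort_config()], sessions are simulated and processed one
#' at a time so a full-size cohort never has to be held in memory.
#'
#' @param x A `faceemg_cohort` (from [simulate_cohort()]) or a
#'   [cohort_config()].
#' @param ... Passed on to methods.
#' @return A `faceemg_analysis` bundle.
#' @export
cohort_analysis <- function(x, ...) UseMethod("cohort_analysis")

#' @rdname cohort_analysis
#' @param schedule Common session schedule (config method only).
#' @param denoise_first See [analyze_session()].
#' @inheritParams session_envelopes
#' @param verbose Print per-subject progress.
#' @export
cohort_analysis.cohort_config <- function(x, schedule = default_study_schedule(),
                                          denoise_first = TRUE, method = "rms",
                                          window_s = 0.25, hop_s = 0.05,
                                          lo_pct = 5, hi_pct = 95,
                                          verbose = FALSE, ...) {
  ids <- sprintf("s%02d", seq_len(x$n_subjects))
  pv <- vector("list", x$n_subjects)
  rt <- vector("list", x$n_subjects)
  for (i in seq_len(x$n_subjects)) {
    sched_i <- dplyr::mutate(schedule, subject_id = ids[i])
    sess <- simulate_session(sched_i, x, subject_seed(x$seed, i),
                             subject_id = ids[i])
    pv[[i]] <- analyze_session(sess$recording, sched_i,
                               denoise_first = denoise_first, method = method,
                               window_s = window_s, hop_s = hop_s,
                               lo_pct = lo_pct, hi_pct = hi_pct)
    rt[[i]] <- sess$ratings
    if (verbose) message("processed subject ", ids[i])
  }
  res <- analyze_cohort_amplitudes(dplyr::bind_rows(pv), dplyr::bind_rows(rt),
                                   schedule)
  res$per_video <- dplyr::bind_rows(pv)
  res
}

#' @rdname cohort_analysis
#' @export
cohort_analysis.faceemg_cohort <- function(x, denoise_first = TRUE,
                                           method = "rms", window_s = 0.25,
                                           hop_s = 0.05, lo_pct = 5,
                                           hi_pct = 95, ...) {
  pv <- purrr::map_dfr(x$sessions, function(sess) {
    sched <- dplyr::mutate(x$schedule,
                           subject_id = sess$recording$subject_id)
    analyze_session(sess$recording, sched, denoise_first = denoise_first,
                    method = method, window_s = window_s, hop_s = hop_s,
                    lo_pct = lo_pct, hi_pct = hi_pct)
  })
  res <- analyze_cohort_amplitudes(pv, x$ratings, x$schedule)
  res$per_video <- pv
  res
}

#' @export
print.faceemg_analysis <- function(x, ...) {
  cat("== Facial sEMG cohort analysis ==\n\n")
  print(x$manipulation)
  cat("\nPaired Wilcoxon families (Bonferroni within family):\n")
  pr <- x$paired
  for (sc in unique(pr$scheme)) {
    sub <- pr[pr$scheme == sc, ]
    cat(sprintf(" %s (m = %d):\n", sc, sub$m[1]))
    for (i in seq_len(nrow(sub))) {
      cat(sprintf("   %-15s %-28s z = %6.3f  p_adj = %-8.3g %s\n",
                  sub$channel[i], sub$contrast[i], sub$z[i], sub$p_adj[i],
                  sub$annotation[i]))
    }
  }
  cat("\nSegmented valence correlations (per-subject-per-level means):\n")
  sg <- x$segment_cors
  for (i in seq_len(nrow(sg))) {
    cat(sprintf("   %-15s %-7s r = %6.3f (p = %-8.3g %s, n = %d)\n",
                sg$channel[i], sg$segment[i], sg$r[i], sg$p[i],
                sg$annotation[i], sg$n[i]))
  }
  cat("\nQuadratic amplitude-vs-valence trends:\n")
  tc <- x$trend_coefficients
  for (i in seq_len(nrow(tc))) {
    cat(sprintf("   %-15s quadratic = %+0.4f, linear = %+0.4f\n",
                tc$channel[i], tc$quadratic[i], tc$linear[i]))
  }
  invisible(x)
}

#' Write an analysis bundle as tidy CSV tables plus a text report
#'
#' @param res A `faceemg_analysis` bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort_results <- function(res, dir) {
  stopifnot(inherits(res, "faceemg_analysis"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    condition_means = file.path(dir, "condition_means.csv"),
    paired_tests = file.path(dir, "paired_tests.csv"),
    segment_correlations = file.path(dir, "segment_correlations.csv"),
    trend_coefficients = file.path(dir, "trend_coefficients.csv"),
    manipulation_summary = file.path(dir, "manipulation_summary.csv"),
    report = file.path(dir, "report.txt")
  )
  readr::write_csv(dplyr::bind_rows(res$condition_means), paths[["condition_means"]])
  readr::write_csv(res$paired, paths[["paired_tests"]])
  readr::write_csv(res$segment_cors, paths[["segment_correlations"]])
  readr::write_csv(res$trend_coefficients, paths[["trend_coefficients"]])
  readr::write_csv(res$manipulation$summary, paths[["manipulation_summary"]])
  sink(paths[["report"]]); on.exit(sink())
  print(res)
  invisible(paths)
}
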