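#' Muscle-by-category effect profile of the synthetic generator
#'
#' The effect profile defines how strongly each muscle activates under each
#' video category, how activation scales with the subject's arousal rating,
#' and the category-conditional distribution the self-reports are drawn from.
#'
#' The defaults encode the group-level structure the analysis is meant to
#' recover: the "positive" muscles (left/right orbicularis oculi and
#' zygomaticus major) activate most for positive videos, somewhat for
#' negative ones (high-arousal content) and least for neutral ones, which
#' yields the characteristic V-shaped amplitude-versus-valence relation; the
#' corrugator activates most for negative videos, least for positive ones,
#' and its arousal coupling is zero. The corrugator's neutral-category gain
#' (1.49) is calibrated so that, under the default rating model and the
#' winsorized-normalized amplitude measure, videos landing in the
#' low-arousal rating bin and those landing in the high-arousal bin have the
#' same expected corrugator amplitude - the corrugator arousal contrast is
#' null by construction (see the methods vignette for the calibration).
#'
#' The default rating model (per-category mean and SD of valence and arousal
#' on the 1-9 scale) is: neutral 4.65 +/- 1.11 valence, 3.41 +/- 1.65
#' arousal; negative 3.18 +/- 1.70, 6.67 +/- 1.40; positive 6.60 +/- 1.26,
#' 5.88 +/- 1.48.
#'
#' @param gain Numeric matrix of activation gain multipliers (>= 0), rows =
#'   [emg_channels()], columns = [video_categories()].
#' @param arousal_coupling Named numeric vector, one multiplier per channel,
#'   applied per unit of subjective arousal above the scale midpoint (see
#'   [simulate_session()]).
#' @param rating_model Tibble with columns `category`, `valence_mean`,
#'   `valence_sd`, `arousal_mean`, `arousal_sd`.
#' @return An object of class `effect_profile`.
#' @export
#' @examples
#' effect_profile()
effect_profile <- function(gain = default_gain_matrix(),
                           arousal_coupling = default_arousal_coupling(),
                           rating_model = default_rating_model()) {
  gain <- as.matrix(gain)
  if (!setequal(rownames(gain), emg_channels()) ||
      !setequal(colnames(gain), video_categories())) {
    rlang::abort("`gain` must have rows emg_channels() and columns video_categories().",
                 class = "faceemg_validation_error")
  }
  gain <- gain[emg_channels(), video_categories(), drop = FALSE]
  if (any(gain < 0)) {
    rlang::abort("Gains must be >= 0.", class = "faceemg_validation_error")
  }
  if (!setequal(names(arousal_coupling), emg_channels())) {
    rlang::abort("`arousal_coupling` must be named by emg_channels().",
                 class = "faceemg_validation_error")
  }
  arousal_coupling <- arousal_coupling[emg_channels()]
  stopifnot(is.data.frame(rating_model),
            all(c("category", "valence_mean", "valence_sd",
                  "arousal_mean", "arousal_sd") %in% names(rating_model)),
            setequal(rating_model$category, video_categories()))
  structure(
    list(gain = gain, arousal_coupling = arousal_coupling,
         rating_model = tibble::as_tibble(rating_model)),
    class = "effect_profile"
  )
}

#' @rdname effect_profile
#' @export
default_gain_matrix <- function() {
  pos_muscles <- c(neutral = 1.0, negative = 1.5, positive = 2.5)
  corr <- c(neutral = 1.49, negative = 2.0, positive = 1.0)
  m <- rbind(
    l_orbicularis = pos_muscles,
    l_zygomaticus = pos_muscles,
    corrugator = corr,
    r_zygomaticus = pos_muscles,
    r_orbicularis = pos_muscles
  )
  m[emg_channels(), video_categories()]
}

#' @rdname effect_profile
#' @export
default_arousal_coupling <- function() {
  c(l_orbicularis = 0.25, l_zygomaticus = 0.25, corrugator = 0,
    r_zygomaticus = 0.25, r_orbicularis = 0.25)
}

#' @rdname effect_profile
#' @export
default_rating_model <- function() {
  tibble::tibble(
    category = c("neutral", "negative", "positive"),
    valence_mean = c(4.65, 3.18, 6.60),
    valence_sd = c(1.11, 1.70, 1.26),
    arousal_mean = c(3.41, 6.67, 5.88),
    arousal_sd = c(1.65, 1.40, 1.48)
  )
}

#' @export
print.effect_profile <- function(x, ...) {
  cat("<effect_profile>\n gains (muscle x category):\n")
  print(round(x$gain, 3))
  cat(" arousal coupling:", paste(sprintf("%s=%.2f", names(x$arousal_coupling),
                                          x$arousal_coupling), collapse = ", "), "\n")
  invisible(x)
}

#' Configuration of a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 38, the study cohort size).
#' @param fs Sampling rate in Hz (default 1000).
#' @param seed Integer seed; the full cohort is a pure function of the
#'   configuration, per-subject seeds are derived from this value.
#' @param effect An [effect_profile()].
#' @param interference_amp Amplitude of the 50 Hz powerline fundamental in
#'   carrier-SD units; harmonic k has amplitude `interference_amp / k`.
#' @param n_harmonics Number of powerline harmonics including the
#'   fundamental (harmonics at or above Nyquist are skipped).
#' @param artifact_level Standard deviation of the sub-20 Hz motion/blink
#'   artifact component, in carrier-SD units.
#' @param emg_band Two-element numeric, the pass band (Hz) of the
#'   band-limited Gaussian EMG carrier; must lie inside (0, fs/2).
#' @param baseline_sd Envelope standard deviation of the carrier at unit
#'   gain, in arbitrary sensor units.
#' @param break_gain Activation gain during inter-video rating breaks.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 38, fs = 1000, seed = 1,
                          effect = effect_profile(),
                          interference_amp = 1, n_harmonics = 3,
                          artifact_level = 2, emg_band = c(20, 450),
                          baseline_sd = 1, break_gain = 1) {
  stopifnot(n_subjects >= 1, fs > 0, length(emg_band) == 2)
  if (emg_band[1] <= 0 || emg_band[2] >= fs / 2 || emg_band[1] >= emg_band[2]) {
    rlang::abort("`emg_band` must satisfy 0 < low < high < fs/2.",
                 class = "faceemg_config_error")
  }
  stopifnot(inherits(effect, "effect_profile"),
            interference_amp >= 0, n_harmonics >= 0, artifact_level >= 0,
            baseline_sd > 0, break_gain >= 0)
  structure(
    list(n_subjects = as.integer(n_subjects), fs = fs, seed = as.integer(seed),
         effect = effect, interference_amp = interference_amp,
         n_harmonics = as.integer(n_harmonics),
         artifact_level = artifact_level, emg_band = emg_band,
         baseline_sd = baseline_sd, break_gain = break_gain),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d subject(s) @ %g Hz, seed %d\n  50 Hz amp %.2f (%d harmonic(s)), artifact %.2f, carrier band %g-%g Hz\n",
    x$n_subjects, x$fs, x$seed, x$interference_amp, x$n_harmonics,
    x$artifact_level, x$emg_band[1], x$emg_band[2]
  ))
  invisible(x)
}

#' The study's fixed 25-video session schedule
#'
#' Videos are presented in four blocks: five neutral (76 s in total), six
#' negative (93 s), five neutral (81 s) and nine positive (78 s), with a
#' fixed inter-video break for self-rating. Each block's duration is split
#' evenly across its videos. Note the per-block durations sum to 328 s of
#' video; see the methods vignette for the bookkeeping of this figure.
#'
#' @param subject_id Subject identifier for the schedule rows.
#' @param break_s Inter-video break duration in seconds (default 10).
#' @return A schedule tibble of 25 events (see [read_schedule()]).
#' @export
#' @examples
#' sched <- default_study_schedule()
#' table(sched$category)
default_study_schedule <- function(subject_id = "s01", break_s = 10) {
  blocks <- list(
    list(category = "neutral", n = 5L, total_s = 76),
    list(category = "negative", n = 6L, total_s = 93),
    list(category = "neutral", n = 5L, total_s = 81),
    list(category = "positive", n = 9L, total_s = 78)
  )
  rows <- list()
  t0 <- 0
  idx <- 0L
  for (b in blocks) {
    dur <- b$total_s / b$n
    for (i in seq_len(b$n)) {
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        subject_id = subject_id,
        video_id = sprintf("v%02d", idx),
        category = b$category,
        start_s = t0,
        end_s = t0 + dur
      )
      t0 <- t0 + dur + break_s
    }
  }
  dplyr::bind_rows(rows)
}

#' Build a custom session schedule
#'
#' Utility for reduced or exploratory protocols: videos of the given
#' categories presented back to back with a fixed inter-video break.
#'
#' @param categories Character vector of video categories in presentation
#'   order.
#' @param duration_s Per-video duration(s) in seconds (recycled).
#' @param break_s Inter-video break in seconds.
#' @param subject_id Subject identifier.
#' @return A schedule tibble (see [read_schedule()]).
#' @export
#' @examples
#' session_schedule(c("neutral", "negative", "positive"), duration_s = 12)
session_schedule <- function(categories, duration_s = 12, break_s = 10,
                             subject_id = "s01") {
  stopifnot(all(categories %in% video_categories()), length(categories) >= 1)
  duration_s <- rep_len(duration_s, length(categories))
  starts <- cumsum(c(0, utils::head(duration_s + break_s, -1)))
  tibble::tibble(
    subject_id = subject_id,
    video_id = sprintf("v%02d", seq_along(categories)),
    category = categories,
    start_s = starts,
    end_s = starts + duration_s
  )
}

# --- signal-synthesis internals ----------------------------------------

# Gaussian white noise band-limited to `band` (ideal FFT-domain band-pass),
# rescaled to unit SD.
band_limited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # two-sided frequency axis
  X[freq < band[1] | freq > band[2]] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  y / stats::sd(y)
}

# Piecewise-constant gain profile over the session with raised-cosine
# transitions (default 100 ms) so amplitude steps do not ring.
gain_profile <- function(schedule, video_gains, n, fs, break_gain,
                         transition_s = 0.1) {
  g <- rep(break_gain, n)
  for (i in seq_len(nrow(schedule))) {
    i0 <- floor(schedule$start_s[i] * fs) + 1L
    i1 <- min(ceiling(schedule$end_s[i] * fs), n)
    if (i0 <= i1) g[i0:i1] <- video_gains[i]
  }
  # raised-cosine crossfade across each gain step
  m <- max(3L, round(transition_s * fs))
  ramp <- 0.5 - 0.5 * cos(pi * seq_len(m) / (m + 1))
  half <- m %/% 2
  for (cp in which(diff(g) != 0)) {
    a <- g[cp]; b <- g[cp + 1L]
    idx <- (cp - half + 1L):(cp - half + m)
    ok <- idx >= 1L & idx <= n
    g[idx[ok]] <- a + (b - a) * ramp[ok]
  }
  g
}

# Sub-20 Hz motion/blink artifact: slow random-walk drift plus
# Poisson-timed ~200 ms biphasic pulses.
artifact_component <- function(n, fs, level, blink_rate_hz = 0.25) {
  if (level <= 0) return(numeric(n))
  # slow drift: random walk sampled at ~2 Hz, smoothed and interpolated to
  # fs; spectral content well below 1 Hz
  fs_slow <- 2
  n_slow <- max(8L, ceiling(n / fs * fs_slow) + 2L)
  walk <- cumsum(stats::rnorm(n_slow))
  drift <- stats::spline(x = (seq_len(n_slow) - 1) / fs_slow, y = walk,
                         xout = (seq_len(n) - 1) / fs, method = "natural")$y
  s <- stats::sd(drift)
  drift <- if (s > 0) drift / s else drift * 0

  blinks <- numeric(n)
  n_blinks <- stats::rpois(1, blink_rate_hz * n / fs)
  if (n_blinks > 0) {
    # biphasic pulse: derivative of a Gaussian, ~200 ms support
    sig <- 0.04 * fs
    tt <- seq(-3 * sig, 3 * sig)
    pulse <- -tt / sig * exp(-tt^2 / (2 * sig^2))
    pulse <- pulse / max(abs(pulse))
    starts <- sort(sample.int(n, n_blinks, replace = TRUE))
    amps <- stats::runif(n_blinks, 2, 5)
    for (j in seq_len(n_blinks)) {
      idx <- starts[j] + seq_along(tt) - 1L
      keep <- idx <= n
      blinks[idx[keep]] <- blinks[idx[keep]] + amps[j] * pulse[keep]
    }
  }
  level * (drift + blinks)
}

powerline_component <- function(n, fs, amp, n_harmonics, base_hz = 50) {
  if (amp <= 0 || n_harmonics < 1) return(numeric(n))
  t <- (seq_len(n) - 1) / fs
  out <- numeric(n)
  for (k in seq_len(n_harmonics)) {
    f <- k * base_hz
    if (f >= fs / 2) break
    out <- out + (amp / k) * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi))
  }
  out
}

# Draw one rating from a discretised truncated normal on 1..9.
draw_ratings <- function(n, mean, sd) {
  pmin(9L, pmax(1L, as.integer(round(stats::rnorm(n, mean, sd)))))
}

#' Simulate one experimental session
#'
#' Generates a multichannel raw sEMG recording plus per-video self-reports
#' for a single subject. Each channel is a band-limited Gaussian carrier
#' whose per-video envelope SD is
#' `baseline_sd * gain(muscle, category) * (1 + coupling(muscle) * (arousal - 5) / 4)`,
#' with 100 ms raised-cosine transitions between videos, plus a 50 Hz
#' powerline sinusoid and harmonics and a sub-20 Hz motion/blink artifact.
#' Ratings are drawn per category from the profile's rating model,
#' rounded and clipped to the 1-9 scale. Output is a pure function of
#' `(schedule, config, subject_seed)`.
#'
#' @param schedule A schedule tibble (e.g. [default_study_schedule()]).
#' @param config A [cohort_config()].
#' @param subject_seed Integer seed for this subject.
#' @param subject_id Subject identifier; defaults to the schedule's.
#' @return A list with elements `recording` ([emg_recording()], stage
#'   `"raw"`) and `ratings` (tibble).
#' @export
#' @examples
#' sched <- default_study_schedule("s01")[1:3, ]
#' cfg <- cohort_config(n_subjects = 1, fs = 250, emg_band = c(20, 100))
#' sess <- simulate_session(sched, cfg, subject_seed = 42)
#' sess$recording
simulate_session <- function(schedule, config, subject_seed,
                             subject_id = schedule$subject_id[1]) {
  stopifnot(inherits(config, "cohort_config"))
  schedule <- validate_schedule(schedule)
  fs <- config$fs
  set.seed(as.integer(subject_seed) %% .Machine$integer.max)

  # session span: last video end plus one trailing rating break
  span_s <- max(schedule$end_s) + 10
  n <- round(span_s * fs)

  rm <- config$effect$rating_model
  idx <- match(schedule$category, rm$category)
  ratings <- tibble::tibble(
    subject_id = subject_id,
    video_id = schedule$video_id,
    valence = draw_ratings(nrow(schedule), rm$valence_mean[idx], rm$valence_sd[idx]),
    arousal = draw_ratings(nrow(schedule), rm$arousal_mean[idx], rm$arousal_sd[idx])
  )

  sig <- tibble::tibble(time_s = (seq_len(n) - 1) / fs)
  for (ch in emg_channels()) {
    base_gain <- config$effect$gain[ch, schedule$category]
    coup <- config$effect$arousal_coupling[[ch]]
    video_gains <- base_gain * (1 + coup * (ratings$arousal - 5) / 4)
    video_gains <- pmax(video_gains, 0)
    g <- gain_profile(schedule, video_gains, n, fs, config$break_gain)
    carrier <- band_limited_noise(n, fs, config$emg_band)
    x <- config$baseline_sd * g * carrier +
      powerline_component(n, fs, config$interference_amp, config$n_harmonics) +
      artifact_component(n, fs, config$artifact_level)
    sig[[ch]] <- x
  }
  list(
    recording = emg_recording(sig, fs = fs, subject_id = subject_id, stage = "raw"),
    ratings = ratings
  )
}

#' Derive the per-subject seed used by [simulate_cohort()]
#' @param seed Cohort seed.
#' @param i Subject index (1-based).
#' @return An integer seed.
#' @export
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate a full cohort
#'
#' Generates `config$n_subjects` sessions on a common schedule, each with a
#' deterministic per-subject seed derived from `config$seed`. Optionally
#' writes all sessions in the on-disk format of [write_recording()].
#'
#' @param config A [cohort_config()].
#' @param schedule Session schedule; subjects share the schedule (as in a
#'   fixed-order stimulus protocol). Defaults to [default_study_schedule()].
#' @param out_dir If non-`NULL`, write signals, schedule and ratings there
#'   and return file paths instead of in-memory objects.
#' @return A list of class `faceemg_cohort` with elements `sessions` (list of
#'   [simulate_session()] results), `schedule`, `ratings` (all subjects) and
#'   `config`; or, with `out_dir`, a list of written paths.
#' @export
simulate_cohort <- function(config, schedule = default_study_schedule(),
                            out_dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- sprintf("s%02d", seq_len(config$n_subjects))
  sessions <- vector("list", config$n_subjects)
  names(sessions) <- ids
  for (i in seq_len(config$n_subjects)) {
    sched_i <- dplyr::mutate(schedule, subject_id = ids[i])
    sessions[[i]] <- simulate_session(sched_i, config, subject_seed(config$seed, i),
                                      subject_id = ids[i])
  }
  ratings <- dplyr::bind_rows(lapply(sessions, `[[`, "ratings"))
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- character(0)
    for (i in seq_along(sessions)) {
      paths <- c(paths, write_recording(sessions[[i]]$recording, out_dir))
    }
    sched_all <- dplyr::bind_rows(lapply(ids, function(id) {
      dplyr::mutate(schedule, subject_id = id)
    }))
    write_schedule(sched_all, file.path(out_dir, "schedule.csv"))
    write_ratings(ratings, file.path(out_dir, "ratings.csv"))
    return(list(recordings = paths,
                schedule = file.path(out_dir, "schedule.csv"),
                ratings = file.path(out_dir, "ratings.csv")))
  }
  structure(
    list(sessions = sessions, schedule = schedule, ratings = ratings,
         config = config),
    class = "faceemg_cohort"
  )
}

#' @export
print.faceemg_cohort <- function(x, ...) {
  cat(sprintf("<faceemg_cohort> %d session(s), %d rating(s), fs %g Hz\n",
              length(x$sessions), nrow(x$ratings), x$config$fs))
  invisible(x)
}
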