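# Shared fixtures for the test suite; everything is generated in code.

# Small, fast configuration: reduced sampling rate and carrier band.
small_config <- function(seed = 1, n_subjects = 1, ...) {
  cohort_config(n_subjects = n_subjects, fs = 250, seed = seed,
                emg_band = c(20, 100), ...)
}

# Null effect profile: equal gains everywhere, no arousal coupling; the
# ratings keep their category structure but amplitudes carry no signal.
null_profile <- function() {
  g <- default_gain_matrix()
  g[, ] <- 1
  effect_profile(gain = g,
                 arousal_coupling = stats::setNames(rep(0, 5), emg_channels()))
}

# Compact mixed-category schedule for quick sessions.
mini_schedule <- function(n_each = 2, duration_s = 10, subject_id = "s01") {
  session_schedule(rep(c("neutral", "negative", "positive"), n_each),
                   duration_s = duration_s, subject_id = subject_id)
}

# One-sided periodogram band power of a real signal.
band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)
  freq <- (seq_len(half + 1) - 1) * fs / n
  p <- Mod(X[seq_len(half + 1)])^2 / n
  sum(p[freq >= lo & freq <= hi])
}

# Long-format envelope tibble from a plain numeric vector.
env_tibble <- function(values, hop_s = 0.05, subject_id = "s01",
                       channel = "l_orbicularis") {
  tibble::tibble(subject_id = subject_id, channel = channel,
                 time_s = (seq_along(values) - 1) * hop_s,
                 amplitude = values)
}

quiet_condition_means <- function(...) {
  rlang::with_options(condition_means(...), rlib_message_verbosity = "quiet")
}

# Six-subject cohort through the full pipeline; reused across test files.
small_cohort_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- small_config(seed = 6, n_subjects = 6)
      sched <- session_schedule(rep(c("neutral", "negative", "positive"), 3),
                                duration_s = 8)
      cache <<- suppressMessages(cohort_analysis(cfg, schedule = sched))
    }
    cache
  }
})
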