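#' Sliding-window amplitude envelope
#'
#' Converts a denoised sEMG signal to an amplitude envelope: for windows of
#' `window_s` seconds placed every `hop_s` seconds, the RMS (square root of
#' the mean power, the default) or the MAV (mean absolute value of the
#' rectified signal). Envelope sample `t` summarises the window *starting*
#' at `(t - 1) * hop_s`; with the defaults (250 ms window, 50 ms hop) the
#' envelope rate is 20 Hz.
#'
#' @param x Numeric signal vector, or an [emg_recording()] (all channels).
#' @param fs Sampling rate in Hz (ignored for recordings).
#' @param method `"rms"` (default) or `"mav"`.
#' @param window_s Window length in seconds.
#' @param hop_s Hop between window starts in seconds; `0 < hop_s <= window_s`.
#' @param ... Passed between methods.
#' @return For a numeric vector, a tibble with columns `time_s` (window start
#'   time) and `amplitude`. For a recording, a long tibble with columns
#'   `subject_id`, `channel`, `time_s`, `amplitude`.
#' @export
#' @examples
#' env <- amplitude_envelope(sin(2 * pi * 10 * seq(0, 1, by = 1e-3)), fs = 1000)
#' head(env)
amplitude_envelope <- function(x, ...) UseMethod("amplitude_envelope")

#' @rdname amplitude_envelope
#' @export
amplitude_envelope.numeric <- function(x, fs, method = c("rms", "mav"),
                                       window_s = 0.25, hop_s = 0.05, ...) {
  method <- match.arg(method)
  if (hop_s <= 0 || hop_s > window_s) {
    rlang::abort("Require 0 < hop_s <= window_s.", class = "faceemg_config_error")
  }
  w <- round(window_s * fs)
  h <- round(hop_s * fs)
  if (w < 2) {
    rlang::abort("Window must span at least 2 samples.", class = "faceemg_config_error")
  }
  n <- length(x)
  if (w > n) {
    rlang::abort("Window longer than signal.", class = "faceemg_validation_error")
  }
  m <- floor((n - w) / h) + 1L
  starts <- (seq_len(m) - 1L) * h
  cs <- c(0, cumsum(if (method == "rms") x^2 else abs(x)))
  acc <- (cs[starts + w + 1L] - cs[starts + 1L]) / w
  vals <- if (method == "rms") sqrt(pmax(acc, 0)) else acc
  tibble::tibble(time_s = starts / fs, amplitude = vals)
}

#' @rdname amplitude_envelope
#' @export
amplitude_envelope.emg_recording <- function(x, method = c("rms", "mav"),
                                             window_s = 0.25, hop_s = 0.05, ...) {
  method <- match.arg(method)
  purrr::map_dfr(recording_channels(x), function(ch) {
    env <- amplitude_envelope(x$signals[[ch]], fs = x$fs, method = method,
                              window_s = window_s, hop_s = hop_s)
    tibble::tibble(subject_id = x$subject_id, channel = ch,
                   time_s = env$time_s, amplitude = env$amplitude)
  })
}

winsorize_vec <- function(x, lo_pct, hi_pct) {
  p <- stats::quantile(x, c(lo_pct, hi_pct) / 100, names = FALSE, na.rm = FALSE)
  out <- x
  out[x < p[1]] <- 0
  out[x > p[2]] <- p[2]
  out
}

normalize_vec <- function(x, warn_context = "") {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    rlang::warn(paste0("Degenerate (constant) envelope", warn_context,
                       "; normalized values set to 0."),
                class = "faceemg_degenerate_channel")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Winsorize an amplitude envelope
#'
#' Envelope values below the subject/channel's `lo_pct` percentile are set to
#' 0 (discarding insignificant activations) and values above the `hi_pct`
#' percentile are clipped to that percentile (suppressing amplitude bursts).
#' The asymmetry - low values go to 0, not to the low percentile - is
#' deliberate and matches the analysis convention this package implements.
#' Percentiles are computed over the full envelope of each subject/channel.
#'
#' @param env Envelope tibble (from [amplitude_envelope()]) or numeric
#'   vector. Tibbles are processed per `subject_id`/`channel` group.
#' @param lo_pct,hi_pct Percentile bounds, defaults 5 and 95.
#' @return Same shape as the input.
#' @export
winsorize_envelope <- function(env, lo_pct = 5, hi_pct = 95) {
  if (!(lo_pct >= 0 && lo_pct < hi_pct && hi_pct <= 100)) {
    rlang::abort("Require 0 <= lo_pct < hi_pct <= 100.", class = "faceemg_config_error")
  }
  if (is.numeric(env)) {
    if (length(env) == 0) {
      rlang::abort("Empty envelope.", class = "faceemg_validation_error")
    }
    return(winsorize_vec(env, lo_pct, hi_pct))
  }
  stopifnot(is.data.frame(env), "amplitude" %in% names(env))
  if (nrow(env) == 0) {
    rlang::abort("Empty envelope.", class = "faceemg_validation_error")
  }
  grp <- intersect(c("subject_id", "channel"), names(env))
  env |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(amplitude = winsorize_vec(.data$amplitude, lo_pct, hi_pct)) |>
    dplyr::ungroup()
}

#' Person-specific min-max normalization of an envelope
#'
#' Maps each subject/channel's (winsorized) envelope to `[0, 1]` by
#' `(x - min) / (max - min)`, with min and max taken over that subject and
#' channel's full session. A constant (degenerate) envelope maps to all
#' zeros with a warning.
#'
#' @param env Envelope tibble or numeric vector (see [winsorize_envelope()]).
#' @return Same shape as the input; non-degenerate output has min 0, max 1.
#' @export
normalize_envelope <- function(env) {
  if (is.numeric(env)) return(normalize_vec(env))
  stopifnot(is.data.frame(env), "amplitude" %in% names(env))
  grp <- intersect(c("subject_id", "channel"), names(env))
  env |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(amplitude = normalize_vec(
      .data$amplitude,
      warn_context = if ("channel" %in% grp) paste0(" (", .data$channel[1], ")") else ""
    )) |>
    dplyr::ungroup()
}

#' Across-sensor average envelope
#'
#' Pointwise arithmetic mean of the five normalized per-muscle envelopes,
#' labelled `"sensors_average"`. All five canonical channels must be present
#' per subject, with equal lengths and values in `[0, 1]`.
#'
#' @param env Long envelope tibble with columns `subject_id`, `channel`,
#'   `time_s`, `amplitude` covering exactly the five canonical channels.
#' @return A tibble of the same shape with `channel = "sensors_average"`.
#' @export
sensor_average <- function(env) {
  stopifnot(is.data.frame(env),
            all(c("subject_id", "channel", "time_s", "amplitude") %in% names(env)))
  for (sid in unique(env$subject_id)) {
    have <- unique(env$channel[env$subject_id == sid])
    missing <- setdiff(emg_channels(), have)
    if (length(missing) > 0) {
      rlang::abort(paste0("Subject ", sid, " lacks channel(s): ",
                          paste(missing, collapse = ", ")),
                   class = "faceemg_validation_error")
    }
    lens <- table(env$channel[env$subject_id == sid])
    if (length(unique(lens)) != 1) {
      rlang::abort(paste0("Subject ", sid, ": channel envelopes differ in length."),
                   class = "faceemg_validation_error")
    }
  }
  if (any(env$amplitude < -1e-9 | env$amplitude > 1 + 1e-9)) {
    rlang::abort("sensor_average() expects normalized envelopes in [0, 1].",
                 class = "faceemg_validation_error")
  }
  wide <- env |>
    dplyr::filter(.data$channel %in% emg_channels()) |>
    tidyr::pivot_wider(id_cols = c("subject_id", "time_s"),
                       names_from = "channel", values_from = "amplitude")
  tibble::tibble(
    subject_id = wide$subject_id,
    channel = sensor_average_label(),
    time_s = wide$time_s,
    amplitude = rowMeans(as.matrix(wide[emg_channels()]))
  )
}

#' Full envelope pipeline for one denoised recording
#'
#' [amplitude_envelope()] then [winsorize_envelope()] then
#' [normalize_envelope()] per channel, with the five-sensor average appended.
#'
#' @param rec A denoised [emg_recording()].
#' @inheritParams amplitude_envelope
#' @param lo_pct,hi_pct Winsorization percentiles.
#' @return Long tibble `subject_id`, `channel`, `time_s`, `amplitude` with
#'   six channels (five muscles + `"sensors_average"`).
#' @export
session_envelopes <- function(rec, method = "rms", window_s = 0.25,
                              hop_s = 0.05, lo_pct = 5, hi_pct = 95) {
  env <- amplitude_envelope(rec, method = method, window_s = window_s,
                            hop_s = hop_s) |>
    winsorize_envelope(lo_pct = lo_pct, hi_pct = hi_pct) |>
    normalize_envelope()
  dplyr::bind_rows(env, sensor_average(env))
}
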