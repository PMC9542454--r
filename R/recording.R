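#' Canonical facial EMG channel labels
#'
#' The five sensor sites analysed by the pipeline, in their canonical
#' left-to-right facial order: left orbicularis oculi, left zygomaticus
#' major, corrugator supercilii, right zygomaticus major, right orbicularis
#' oculi. The frontalis sites present on some devices are deliberately not
#' part of the analysis surface.
#'
#' @return Character vector of the five channel labels.
#' @export
#' @examples
#' emg_channels()
emg_channels <- function() {
  c("l_orbicularis", "l_zygomaticus", "corrugator", "r_zygomaticus",
    "r_orbicularis")
}

#' Label used for the across-sensor average pseudo-channel
#' @return A length-one character vector.
#' @export
sensor_average_label <- function() "sensors_average"

emg_stages <- function() c("raw", "denoised", "envelope", "normalized")

#' Construct a multichannel facial EMG recording
#'
#' An `emg_recording` bundles a wide signal table (one `time_s` column plus
#' one column per channel, in canonical [emg_channels()] order) with its
#' sampling rate, subject identifier and processing stage.
#'
#' @param signals A data frame with a numeric `time_s` column and one numeric
#'   column per channel. Channels are reordered into canonical order.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param subject_id Subject identifier (length-one character).
#' @param stage Processing stage, one of `"raw"`, `"denoised"`, `"envelope"`,
#'   `"normalized"`.
#' @return An object of class `emg_recording`.
#' @export
#' @examples
#' sig <- tibble::tibble(
#'   time_s = seq(0, 0.999, by = 0.001),
#'   l_orbicularis = rnorm(1000), l_zygomaticus = rnorm(1000),
#'   corrugator = rnorm(1000), r_zygomaticus = rnorm(1000),
#'   r_orbicularis = rnorm(1000)
#' )
#' emg_recording(sig, fs = 1000, subject_id = "s01")
emg_recording <- function(signals, fs, subject_id, stage = "raw") {
  stopifnot(is.data.frame(signals))
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    rlang::abort("`subject_id` must be a single string.", class = "faceemg_validation_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    rlang::abort("`fs` must be a positive number (Hz).", class = "faceemg_validation_error")
  }
  stage <- match.arg(stage, emg_stages())
  if (!"time_s" %in% names(signals)) {
    rlang::abort("`signals` must contain a `time_s` column.", class = "faceemg_format_error")
  }
  chans <- setdiff(names(signals), "time_s")
  unknown <- setdiff(chans, emg_channels())
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Unknown channel column(s): ", paste(unknown, collapse = ", "),
             ". Valid channels: ", paste(emg_channels(), collapse = ", "), "."),
      class = "faceemg_format_error"
    )
  }
  if (anyDuplicated(chans)) {
    rlang::abort("Duplicate channel columns.", class = "faceemg_format_error")
  }
  if (nrow(signals) < 1L) {
    rlang::abort("Recording must contain at least one sample.", class = "faceemg_validation_error")
  }
  chans <- intersect(emg_channels(), chans)
  signals <- tibble::as_tibble(signals)[, c("time_s", chans)]
  if (is.unsorted(signals$time_s, strictly = TRUE)) {
    rlang::abort("`time_s` must be strictly increasing.", class = "faceemg_format_error")
  }
  if (stage == "normalized") {
    vals <- unlist(signals[chans], use.names = FALSE)
    if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE)) {
      rlang::abort("stage = 'normalized' requires all values in [0, 1].",
                   class = "faceemg_validation_error")
    }
  }
  structure(
    list(subject_id = subject_id, fs = fs, stage = stage, signals = signals),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  chans <- setdiff(names(x$signals), "time_s")
  cat(sprintf(
    "<emg_recording> subject %s | stage %s | %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$stage, length(chans), nrow(x$signals), x$fs,
    nrow(x$signals) / x$fs
  ))
  cat("  channels:", paste(chans, collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @export
as_tibble.emg_recording <- function(x, ...) x$signals

#' Duration of a recording in seconds
#' @param rec An [emg_recording()].
#' @return Duration in seconds (`n_samples / fs`).
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "emg_recording"))
  nrow(rec$signals) / rec$fs
}

#' Channel labels present in a recording
#' @param rec An [emg_recording()].
#' @return Character vector of channel labels in canonical order.
#' @export
recording_channels <- function(rec) setdiff(names(rec$signals), "time_s")
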