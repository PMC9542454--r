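#' Muscle-specific filter specification
#'
#' Facial muscles carry genuine sEMG power close to the motion-artifact band,
#' so the high-pass cutoff is chosen per muscle: 30 Hz for the corrugator
#' supercilii and 20 Hz for the orbicularis oculi and zygomaticus major
#' sites. The nominal low-pass cutoff is 500 Hz (sEMG power above that is
#' negligible); because a 500 Hz cutoff is unrealizable at a 1000 Hz sampling
#' rate, the effective cutoff is `min(500, 0.45 * fs)` - 450 Hz for the
#' study's 1000 Hz recordings.
#'
#' @param muscle One of [emg_channels()].
#' @param fs Sampling rate in Hz.
#' @param order Butterworth filter order (applied forward-backward).
#' @return A list of class `filter_spec` with fields `muscle`,
#'   `hp_cutoff_hz`, `lp_cutoff_hz`, `order`, `zero_phase`.
#' @export
#' @examples
#' design_filters("corrugator", fs = 1000)
#' design_filters("l_zygomaticus", fs = 2000)
design_filters <- function(muscle, fs, order = 4) {
  if (!muscle %in% emg_channels()) {
    rlang::abort(
      paste0("Unknown muscle '", muscle, "'. Valid labels: ",
             paste(emg_channels(), collapse = ", "), "."),
      class = "faceemg_validation_error"
    )
  }
  hp <- if (muscle == "corrugator") 30 else 20
  lp <- min(500, 0.45 * fs)
  if (hp >= lp) {
    rlang::abort("Sampling rate too low for the muscle's pass band.",
                 class = "faceemg_config_error")
  }
  structure(
    list(muscle = muscle, hp_cutoff_hz = hp, lp_cutoff_hz = lp,
         order = order, zero_phase = TRUE),
    class = "filter_spec"
  )
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> %s: band %g-%g Hz, Butterworth order %d, zero-phase\n",
              x$muscle, x$hp_cutoff_hz, x$lp_cutoff_hz, x$order))
  invisible(x)
}

#' Zero-phase band-limiting of one channel
#'
#' Applies the spec's high-pass and/or low-pass Butterworth filters
#' forward-backward (zero net group delay, squared magnitude response).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [design_filters()] specification.
#' @param which `"both"` (default), `"high"` or `"low"`.
#' @return Filtered signal, same length as `x`.
#' @export
filter_channel <- function(x, fs, spec, which = c("both", "high", "low")) {
  which <- match.arg(which)
  stopifnot(inherits(spec, "filter_spec"))
  if (length(x) <= 3 * (spec$order + 1)) {
    rlang::abort("Signal too short for the requested filter order.",
                 class = "faceemg_validation_error")
  }
  if (spec$lp_cutoff_hz >= fs / 2) {
    rlang::abort("Low-pass cutoff must be below Nyquist.",
                 class = "faceemg_config_error")
  }
  y <- x
  if (which %in% c("both", "high")) {
    bf <- signal::butter(spec$order, spec$hp_cutoff_hz / (fs / 2), type = "high")
    y <- signal::filtfilt(bf, y)
  }
  if (which %in% c("both", "low")) {
    bf <- signal::butter(spec$order, spec$lp_cutoff_hz / (fs / 2), type = "low")
    y <- signal::filtfilt(bf, y)
  }
  y
}

# Precompute, for a transform length L, the bin indices and interpolation
# weights of every harmonic notch: which positive-frequency bins get
# replaced, the flanking bins their target magnitude is interpolated from,
# and the conjugate-symmetric mirror bins.
make_interp_plan <- function(L, fs, base_hz, max_harmonic_hz,
                             notch_halfwidth_hz, flank_hz) {
  half <- floor(L / 2)
  freq <- (seq_len(half + 1) - 1) * fs / L  # bins 1..half+1 = 0..Nyquist
  harmonics <- seq(base_hz, min(max_harmonic_hz, fs / 2 - notch_halfwidth_hz),
                   by = base_hz)
  if (length(harmonics) == 0) return(list())
  in_any_notch <- rep(FALSE, half + 1)
  for (h in harmonics) {
    in_any_notch <- in_any_notch | abs(freq - h) <= notch_halfwidth_hz
  }
  plan <- list()
  for (h in harmonics) {
    notch <- which(abs(freq - h) <= notch_halfwidth_hz)
    if (length(notch) == 0) next
    left <- which(freq >= h - flank_hz[2] & freq <= h - flank_hz[1] & !in_any_notch)
    right <- which(freq >= h + flank_hz[1] & freq <= h + flank_hz[2] & !in_any_notch)
    if (length(left) == 0 && length(right) == 0) next
    f_l <- h - mean(flank_hz); f_r <- h + mean(flank_hz)
    conj_idx <- L - notch + 2L
    keep <- notch > 1L & conj_idx <= L & conj_idx != notch
    plan[[length(plan) + 1L]] <- list(
      notch = notch, left = left, right = right,
      # weight of the right flank mean in the linear interpolation
      w_right = (freq[notch] - f_l) / (f_r - f_l),
      conj_from = notch[keep], conj_to = conj_idx[keep]
    )
  }
  plan
}

# Apply a precomputed interpolation plan to a full-length complex spectrum,
# preserving phase; returns the modified spectrum.
interpolate_harmonics <- function(X, plan) {
  for (p in plan) {
    old <- Mod(X[p$notch])
    m_l <- if (length(p$left) > 0) mean(Mod(X[p$left])) else mean(Mod(X[p$right]))
    m_r <- if (length(p$right) > 0) mean(Mod(X[p$right])) else mean(Mod(X[p$left]))
    target <- pmax(m_l + (m_r - m_l) * p$w_right, 0)
    scale <- ifelse(old > 0, target / old, 0)
    X[p$notch] <- X[p$notch] * scale
    X[p$notch[old == 0]] <- target[old == 0]  # zero bins get zero phase
    X[p$conj_to] <- Conj(X[p$conj_from])
  }
  X
}

#' Suppress powerline interference by spectrum interpolation
#'
#' Electromagnetic interference appears as narrow spectral lines at the mains
#' frequency and its harmonics. Rather than notch-filtering (which removes
#' genuine sEMG power at those frequencies), the amplitude spectrum inside a
#' narrow band around each harmonic is replaced by a linear interpolation of
#' the mean magnitudes of the stable flanking bands, phases are preserved,
#' and the signal is reconstructed by the inverse transform. By default the
#' whole recording is processed in a single transform, so bins outside the
#' notch bands are untouched by construction and the phase of every bin is
#' preserved exactly. A finite `segment_s` switches to half-overlapping
#' Hann-windowed segments, which track slow drift of the interference
#' amplitude at the cost of slightly blurring the replaced bands (a strong
#' stationary line leaves a small coherent residual in segmented mode, since
#' the replaced bins keep the line's phase in every segment).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param base_hz Mains fundamental (default 50).
#' @param max_harmonic_hz Highest harmonic frequency to process (default 450).
#' @param notch_halfwidth_hz Half-width of the replaced band (default 0.5).
#'   In segmented mode this is widened by the analysis window's main-lobe
#'   width (`2 / segment_s` Hz) so a pure interference line's spectral
#'   leakage is fully covered.
#' @param flank_hz Two-element numeric: the flanking band spans
#'   `flank_hz[1]` to `flank_hz[2]` Hz on each side of the harmonic
#'   (default `c(1, 3.5)`), excluding other notch bands.
#' @param segment_s Segment length in seconds; the default `Inf` processes
#'   the whole signal in one transform.
#' @return The cleaned signal, same length as `x`.
#' @export
suppress_powerline <- function(x, fs, base_hz = 50, max_harmonic_hz = 450,
                               notch_halfwidth_hz = 0.5, flank_hz = c(1, 3.5),
                               segment_s = Inf) {
  if (base_hz >= fs / 2) {
    rlang::abort("`base_hz` must be below Nyquist.", class = "faceemg_config_error")
  }
  n <- length(x)
  L <- if (is.finite(segment_s)) round(segment_s * fs) else n
  if (L >= n) {
    plan <- make_interp_plan(n, fs, base_hz, max_harmonic_hz,
                             notch_halfwidth_hz, flank_hz)
    X <- interpolate_harmonics(stats::fft(x), plan)
    return(Re(stats::fft(X, inverse = TRUE)) / n)
  }
  hop <- floor(L / 2)
  L <- 2L * hop
  # a spectral line seen through the Hann analysis window spreads over a
  # main lobe of +/- 2 bins; widen the replaced band accordingly so the
  # line's leakage is covered
  eff_halfwidth <- notch_halfwidth_hz + 2 * fs / L
  plan <- make_interp_plan(L, fs, base_hz, max_harmonic_hz,
                           eff_halfwidth, flank_hz)
  # periodic Hann analysis window; 50% overlap-add reconstructs exactly
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / L)
  y <- numeric(n)
  wsum <- numeric(n)
  starts <- seq(1L - hop, n, by = hop)
  for (s in starts) {
    idx <- s:(s + L - 1L)
    inside <- idx >= 1L & idx <= n
    seg <- numeric(L)
    seg[inside] <- x[idx[inside]]
    X <- interpolate_harmonics(stats::fft(seg * w), plan)
    rec <- Re(stats::fft(X, inverse = TRUE)) / L
    y[idx[inside]] <- y[idx[inside]] + rec[inside]
    wsum[idx[inside]] <- wsum[idx[inside]] + w[inside]
  }
  ok <- wsum > 1e-12
  y[ok] <- y[ok] / wsum[ok]
  y[!ok] <- x[!ok]
  y
}

#' Denoise a raw recording
#'
#' Per channel, in fixed order: muscle-specific zero-phase high-pass
#' (removes sub-20/30 Hz motion and blink artifacts), powerline-harmonic
#' suppression by spectrum interpolation, then the zero-phase low-pass.
#'
#' @param rec An [emg_recording()] with `stage = "raw"`.
#' @param base_hz Mains fundamental in Hz (default 50).
#' @param max_harmonic_hz Highest harmonic processed; defaults to the
#'   effective low-pass cutoff.
#' @param segment_s Spectrum-interpolation segment length in seconds; see
#'   [suppress_powerline()].
#' @return The recording with `stage = "denoised"`.
#' @export
denoise <- function(rec, base_hz = 50, max_harmonic_hz = NULL, segment_s = Inf) {
  stopifnot(inherits(rec, "emg_recording"))
  if (rec$stage != "raw") {
    rlang::abort(paste0("denoise() expects stage = 'raw', got '", rec$stage, "'."),
                 class = "faceemg_validation_error")
  }
  sig <- rec$signals
  for (ch in recording_channels(rec)) {
    spec <- design_filters(ch, rec$fs)
    mh <- if (is.null(max_harmonic_hz)) spec$lp_cutoff_hz else max_harmonic_hz
    y <- filter_channel(sig[[ch]], rec$fs, spec, which = "high")
    y <- suppress_powerline(y, rec$fs, base_hz = base_hz, max_harmonic_hz = mh,
                            segment_s = segment_s)
    y <- filter_channel(y, rec$fs, spec, which = "low")
    sig[[ch]] <- y
  }
  emg_recording(sig, fs = rec$fs, subject_id = rec$subject_id, stage = "denoised")
}
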