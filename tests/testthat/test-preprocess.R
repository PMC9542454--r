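test_that("filter design encodes the muscle-specific cutoffs", {
  spec <- design_filters("corrugator", fs = 2000)
  expect_equal(spec$hp_cutoff_hz, 30)
  expect_equal(spec$lp_cutoff_hz, 500)

  for (m in setdiff(emg_channels(), "corrugator")) {
    expect_equal(design_filters(m, fs = 2000)$hp_cutoff_hz, 20)
  }

  # the nominal 500 Hz low-pass is capped below Nyquist at 1000 Hz
  expect_equal(design_filters("l_orbicularis", fs = 1000)$lp_cutoff_hz, 450)

  expect_error(design_filters("frontalis", fs = 1000), "l_orbicularis",
               class = "faceemg_validation_error")
})

test_that("zero-phase band-limiting attenuates stop band and passes pass band", {
  fs <- 1000
  t <- (0:(20 * fs - 1)) / fs
  spec <- design_filters("l_orbicularis", fs)
  mid <- (5 * fs):(15 * fs)  # avoid edge transients

  low_tone <- sin(2 * pi * 5 * t)
  out <- filter_channel(low_tone, fs, spec, which = "high")
  expect_lt(sqrt(mean(out[mid]^2)) / sqrt(mean(low_tone^2)), 0.01)

  pass_tone <- sin(2 * pi * 100 * t)
  out <- filter_channel(pass_tone, fs, spec)
  expect_lt(abs(sqrt(mean(out[mid]^2)) / sqrt(mean(pass_tone^2)) - 1), 0.05)

  expect_equal(filter_channel(numeric(1000), fs, spec), numeric(1000))
  expect_error(filter_channel(numeric(10), fs, spec),
               class = "faceemg_validation_error")
  # >= 40 dB one octave below the high-pass cutoff (10 Hz for a 20 Hz cutoff)
  oct_tone <- sin(2 * pi * 10 * t)
  out <- filter_channel(oct_tone, fs, spec, which = "high")
  expect_lt(20 * log10(sqrt(mean(out[mid]^2)) / sqrt(mean(oct_tone^2))), -40)
})

test_that("band-limiting is zero-phase (cross-correlation peaks at lag 0)", {
  set.seed(1)
  fs <- 1000
  spec <- design_filters("l_zygomaticus", fs)
  x <- band_limited <- signal::filtfilt(signal::butter(4, c(30, 200) / (fs / 2), "pass"),
                                        stats::rnorm(10 * fs))
  y <- filter_channel(x, fs, spec)
  cc <- stats::ccf(x, y, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("spectrum interpolation flattens tones into the flanking noise floor", {
  set.seed(7)
  fs <- 1000
  n <- 30 * fs
  t <- (seq_len(n) - 1) / fs
  carrier <- signal::filtfilt(signal::butter(4, c(20, 450) / (fs / 2), "pass"),
                              stats::rnorm(n))
  p_carrier <- mean(carrier^2)
  tone <- sqrt(2 * 10 * p_carrier) * sin(2 * pi * 50 * t)  # 10x band power
  x <- carrier + tone

  y <- suppress_powerline(x, fs)
  p_notch <- band_power(y, fs, 49.5, 50.5)
  p_flank <- (band_power(y, fs, 46, 48.5) + band_power(y, fs, 51.5, 54)) / 2 /
    2.5  # per-Hz normalization: flanks span 2.5 Hz vs 1 Hz notch
  expect_lt(abs(10 * log10(p_notch / p_flank)), 3)

  # broadband noise with no interference: near-idempotent
  y0 <- suppress_powerline(carrier, fs)
  expect_lt(abs(mean(y0^2) - mean(carrier^2)) / mean(carrier^2), 0.02)
})

test_that("all requested harmonics are attenuated >= 20 dB", {
  set.seed(8)
  fs <- 1000
  n <- 20 * fs
  t <- (seq_len(n) - 1) / fs
  carrier <- signal::filtfilt(signal::butter(4, c(20, 450) / (fs / 2), "pass"),
                              stats::rnorm(n))
  amp <- sqrt(2 * 10 * mean(carrier^2))
  x <- carrier
  for (f in c(50, 100, 150)) x <- x + amp * sin(2 * pi * f * t)
  # both the whole-signal default and the segmented drift-tracking mode
  for (seg in c(Inf, 2)) {
    y <- suppress_powerline(x, fs, max_harmonic_hz = 500, segment_s = seg)
    for (f in c(50, 100, 150)) {
      before <- band_power(x, fs, f - 0.5, f + 0.5)
      after <- band_power(y, fs, f - 0.5, f + 0.5)
      expect_lt(10 * log10(after / before), -20)
    }
  }
  expect_error(suppress_powerline(x, fs, base_hz = 600),
               class = "faceemg_config_error")
})

test_that("whole-signal interpolation leaves out-of-notch bins bit-identical", {
  set.seed(9)
  fs <- 500
  x <- stats::rnorm(4 * fs)
  y <- suppress_powerline(x, fs, segment_s = Inf, max_harmonic_hz = 200)
  n <- length(x)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  in_notch <- rep(FALSE, n)
  for (h in c(50, 100, 150, 200)) in_notch <- in_notch | abs(freq - h) <= 0.5
  Mx <- Mod(stats::fft(x))
  My <- Mod(stats::fft(y))
  expect_lt(max(abs(Mx[!in_notch] - My[!in_notch])) / max(Mx), 1e-12)
})

test_that("denoise removes artifact and interference together", {
  sched <- session_schedule(rep("neutral", 3), duration_s = 15)
  cfg <- cohort_config(n_subjects = 1, fs = 1000, seed = 1,
                       interference_amp = 2, n_harmonics = 3,
                       artifact_level = 3)
  sess <- simulate_session(sched, cfg, subject_seed = 21)
  den <- denoise(sess$recording)
  expect_identical(den$stage, "denoised")
  for (ch in c("l_orbicularis", "corrugator")) {
    x <- sess$recording$signals[[ch]]
    y <- den$signals[[ch]]
    expect_lt(10 * log10(band_power(y, 1000, 0.1, 20) /
                           band_power(x, 1000, 0.1, 20)), -20)
    expect_lt(10 * log10(band_power(y, 1000, 49.5, 50.5) /
                           band_power(x, 1000, 49.5, 50.5)), -20)
  }
  expect_error(denoise(den), class = "faceemg_validation_error")
})

test_that("a clean band-limited carrier passes through denoising nearly unchanged", {
  sched <- session_schedule(rep("neutral", 2), duration_s = 15)
  cfg <- cohort_config(n_subjects = 1, fs = 1000, seed = 1,
                       interference_amp = 0, n_harmonics = 0,
                       artifact_level = 0, emg_band = c(35, 400),
                       effect = null_profile())
  sess <- simulate_session(sched, cfg, subject_seed = 5)
  den <- denoise(sess$recording)
  for (ch in emg_channels()) {
    ratio <- sqrt(mean(den$signals[[ch]]^2)) /
      sqrt(mean(sess$recording$signals[[ch]]^2))
    expect_gte(ratio, 0.9)
    expect_lte(ratio, 1.0)
  }
})
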