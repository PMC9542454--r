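test_that("envelope extraction matches closed forms", {
  fs <- 1000
  const <- rep(-3, 2 * fs)
  env <- amplitude_envelope(const, fs, method = "rms")
  expect_true(all(abs(env$amplitude - 3) < 1e-12))
  env <- amplitude_envelope(const, fs, method = "mav")
  expect_true(all(abs(env$amplitude - 3) < 1e-12))

  # RMS of a sinusoid over an integer number of periods is A / sqrt(2)
  A <- 2.5
  x <- A * sin(2 * pi * 10 * (0:(2 * fs - 1)) / fs)
  env <- amplitude_envelope(x, fs, method = "rms", window_s = 0.2, hop_s = 0.1)
  expect_true(all(abs(env$amplitude - A / sqrt(2)) < 1e-6))

  # envelope length and timing contract
  env <- amplitude_envelope(stats::rnorm(1000), fs, window_s = 0.25, hop_s = 0.05)
  expect_equal(nrow(env), floor((1000 / fs - 0.25) / 0.05) + 1)
  expect_equal(env$time_s, (seq_len(nrow(env)) - 1) * 0.05)

  expect_error(amplitude_envelope(stats::rnorm(10), fs, window_s = 0.25),
               class = "faceemg_validation_error")
  expect_error(amplitude_envelope(stats::rnorm(100), fs, window_s = 0.05,
                                  hop_s = 0.1),
               class = "faceemg_config_error")
})

test_that("envelopes equal a naive per-window loop on random signals", {
  set.seed(10)
  fs <- 200
  for (rep in 1:20) {
    n <- sample(300:800, 1)
    x <- stats::rnorm(n)
    w_s <- sample(c(0.1, 0.25, 0.5), 1)
    h_s <- sample(c(0.05, 0.1), 1)
    w <- round(w_s * fs); h <- round(h_s * fs)
    m <- floor((n - w) / h) + 1
    naive_rms <- vapply(seq_len(m), function(t) {
      win <- x[((t - 1) * h + 1):((t - 1) * h + w)]
      sqrt(mean(win^2))
    }, numeric(1))
    naive_mav <- vapply(seq_len(m), function(t) {
      mean(abs(x[((t - 1) * h + 1):((t - 1) * h + w)]))
    }, numeric(1))
    expect_equal(amplitude_envelope(x, fs, "rms", w_s, h_s)$amplitude, naive_rms)
    expect_equal(amplitude_envelope(x, fs, "mav", w_s, h_s)$amplitude, naive_mav)
    # power-mean inequality, windowwise
    expect_true(all(naive_rms >= naive_mav - 1e-12))
  }
})

test_that("winsorization zeroes the low tail and clips the high tail", {
  x <- as.numeric(1:100)
  p <- stats::quantile(x, c(0.05, 0.95), names = FALSE)
  w <- winsorize_envelope(x)
  expect_true(all(w[x < p[1]] == 0))
  expect_true(all(w[x > p[2]] == p[2]))
  expect_identical(w[x >= p[1] & x <= p[2]], x[x >= p[1] & x <= p[2]])

  # degenerate constant envelope is unchanged
  expect_identical(winsorize_envelope(rep(2, 50)), rep(2, 50))

  # near-idempotence: re-application can only shrink values, and barely
  set.seed(11)
  e <- abs(stats::rnorm(500))
  w1 <- winsorize_envelope(e)
  w2 <- winsorize_envelope(w1)
  expect_true(all(w2 <= w1 + 1e-12))
  expect_lt(sqrt(mean((w2 - w1)^2)) / stats::sd(w1), 0.05)
  expect_true(all(w2[w1 == 0] == 0))

  expect_error(winsorize_envelope(numeric(0)), class = "faceemg_validation_error")
})

test_that("min-max normalization maps to [0, 1] and flags degenerate channels", {
  expect_equal(normalize_envelope(c(0, 2, 4)), c(0, 0.5, 1))
  expect_warning(z <- normalize_envelope(rep(3, 10)),
                 class = "faceemg_degenerate_channel")
  expect_equal(z, rep(0, 10))
  set.seed(12)
  for (rep in 1:10) {
    e <- winsorize_envelope(abs(stats::rnorm(200)))
    z <- normalize_envelope(e)
    expect_equal(min(z), 0)
    expect_equal(max(z), 1)
  }
})

test_that("grouped envelope tables are winsorized and normalized per channel", {
  set.seed(13)
  env <- dplyr::bind_rows(
    env_tibble(abs(stats::rnorm(100, 5)), channel = "l_orbicularis"),
    env_tibble(abs(stats::rnorm(100, 50, 10)), channel = "corrugator")
  )
  out <- normalize_envelope(winsorize_envelope(env))
  per_ch <- out |>
    dplyr::group_by(channel) |>
    dplyr::summarise(min = min(amplitude), max = max(amplitude))
  expect_equal(per_ch$min, c(0, 0))
  expect_equal(per_ch$max, c(1, 1))
})

test_that("sensor averaging is the pointwise mean over the five channels", {
  n <- 50
  base <- env_tibble(seq(0, 1, length.out = n))
  env5 <- dplyr::bind_rows(lapply(emg_channels(), function(ch) {
    dplyr::mutate(base, channel = ch)
  }))
  avg <- sensor_average(env5)
  expect_identical(unique(avg$channel), sensor_average_label())
  expect_equal(avg$amplitude, base$amplitude)

  consts <- c(0, 0, 0, 0, 1)
  env5$amplitude <- rep(consts, each = n)
  expect_equal(sensor_average(env5)$amplitude, rep(0.2, n))

  set.seed(14)
  env5$amplitude <- stats::runif(5 * n)
  avg <- sensor_average(env5)
  oracle <- colMeans(matrix(env5$amplitude, nrow = 5, byrow = TRUE))
  expect_equal(avg$amplitude, oracle)

  expect_error(sensor_average(env5[env5$channel != "corrugator", ]),
               "corrugator", class = "faceemg_validation_error")
})

test_that("the envelope pipeline is invariant to channel scale", {
  sched <- mini_schedule(n_each = 1)
  sess <- simulate_session(sched, small_config(seed = 4), subject_seed = 9)
  rec <- sess$recording
  scaled <- rec
  for (ch in emg_channels()) scaled$signals[[ch]] <- 37.5 * scaled$signals[[ch]]
  env_a <- session_envelopes(denoise(rec))
  env_b <- session_envelopes(denoise(scaled))
  expect_lt(max(abs(env_a$amplitude - env_b$amplitude)), 1e-9)
})
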