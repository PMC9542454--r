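# Brute-force references used as independent oracles -----------------------

friedman_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  R <- t(apply(x, 1, rank))
  stat <- 12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
  ties <- sum(apply(x, 1, function(r) {
    tt <- as.numeric(table(r)); sum(tt^3 - tt)
  }))
  stat / (1 - ties / (n * k * (k^2 - 1)))
}

# Exact two-sided signed-rank p by enumerating all sign assignments.
wilcoxon_enum_p <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  n <- length(d)
  w_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  w_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  # two-sided: as extreme in either direction
  min(1, 2 * min(mean(w_all >= w_obs), mean(w_all <= w_obs)))
}

test_that("Friedman statistic matches closed forms and stats::friedman.test", {
  # perfect concordance, k = 3: chi2 = 2n, ranks 1/2/3
  m <- matrix(rep(c(1, 5, 9), each = 5), nrow = 5)
  res <- friedman_rank_test(m)
  expect_equal(res$chi2, 10)
  expect_equal(unname(res$mean_ranks), c(1, 2, 3))
  expect_equal(mean(res$mean_ranks), (res$k + 1) / 2)

  # constant matrix: all mid-ranks tie, chi2 = 0
  expect_equal(friedman_rank_test(matrix(1, 4, 3))$chi2, 0)

  set.seed(20)
  for (rep in 1:25) {
    n <- sample(4:10, 1); k <- sample(3:5, 1)
    x <- matrix(stats::rnorm(n * k), n, k)
    if (rep %% 3 == 0) x <- round(x)  # induce ties
    res <- friedman_rank_test(x)
    expect_equal(res$chi2, friedman_oracle(x), tolerance = 1e-12)
    ref <- stats::friedman.test(x)
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(mean(res$mean_ranks), (k + 1) / 2)
  }

  expect_error(friedman_rank_test(matrix(c(1, NA, 2, 3), 2, 2)),
               class = "faceemg_validation_error")
})

test_that("signed-rank test matches exact enumeration and stats::wilcox.test", {
  # identical pairs are degenerate
  expect_error(wilcoxon_signed_rank(1:6, 1:6),
               class = "faceemg_degenerate_comparison")

  set.seed(21)
  for (rep in 1:20) {
    n <- 8
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$p, wilcoxon_enum_p(x - y), tolerance = 1e-12)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
    expect_equal(res$statistic, unname(ref$statistic))
    # normal approximation within its documented error of the exact law
    p_norm <- 2 * stats::pnorm(-abs(res$z))
    expect_lt(abs(p_norm - res$p), 0.1)
  }

  # all-positive differences at n = 20: the smallest exact two-sided p
  y <- stats::rnorm(20)
  x <- y + stats::runif(20, 0.5, 1.5)
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$p, 2 * 2^-20)
  expect_gt(res$z, 0)

  # large/tied samples use the tie-corrected normal approximation
  set.seed(22)
  x <- sample(1:9, 40, replace = TRUE)
  y <- sample(1:9, 40, replace = TRUE)
  keep <- x != y
  res <- wilcoxon_signed_rank(x[keep], y[keep])
  ref <- stats::wilcox.test(x[keep], y[keep], paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  expect_identical(res$method, "normal")

  # sign convention: z > 0 when the first sample tends to be larger
  expect_gt(wilcoxon_signed_rank(2:11, (2:11) - 3)$z, 0)
  expect_lt(wilcoxon_signed_rank(2:11, (2:11) + 3)$z, 0)
})

test_that("Bonferroni adjustment caps at one and is monotone", {
  expect_equal(bonferroni_adjust(0.01, 6), 0.06)
  expect_equal(bonferroni_adjust(0.3, 6), 1)
  expect_equal(bonferroni_adjust(0.002, 18), 0.036)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(bonferroni_adjust(p, 6)) >= 0))
  expect_true(all(bonferroni_adjust(p, 12) >= bonferroni_adjust(p, 6)))
  expect_equal(bonferroni_adjust(bonferroni_adjust(0.5, 6), 1),
               bonferroni_adjust(0.5, 6))
})

test_that("star annotations follow the half-open significance bands", {
  expect_identical(p_stars(c(0.5, 0.06, 0.05, 0.03, 0.01, 0.005, 0.001,
                             5e-4, 1e-4, 5e-5)),
                   c("ns", "ns", "*", "*", "**", "**", "***", "***",
                     "****", "****"))
  expect_true(is.na(p_stars(NA_real_)))
})

test_that("paired families have the right shape and family sizes", {
  set.seed(23)
  subjects <- sprintf("s%02d", 1:12)
  chans <- c(emg_channels(), sensor_average_label())
  bin_means <- tidyr::expand_grid(subject_id = subjects, channel = chans,
                                  condition = c("V_negative", "V_positive")) |>
    dplyr::mutate(scheme = "valence_bin",
                  value = stats::runif(dplyr::n()), n_videos = 5L)
  res <- paired_amplitude_analysis(bin_means)
  expect_equal(nrow(res), 6L)
  expect_true(all(res$m == 6))
  expect_true(all(res$p_adj >= res$p_raw))
  expect_identical(res$annotation, p_stars(res$p_adj))

  vt_means <- tidyr::expand_grid(subject_id = subjects, channel = chans,
                                 condition = paste0("W_", video_categories())) |>
    dplyr::mutate(scheme = "video_type",
                  value = stats::runif(dplyr::n()), n_videos = 6L)
  res <- paired_amplitude_analysis(vt_means)
  expect_equal(nrow(res), 18L)
  expect_true(all(res$m == 18))

  # too few complete pairs is reported, not fatal
  small <- dplyr::filter(bin_means, subject_id %in% subjects[1:3])
  res <- paired_amplitude_analysis(small)
  expect_true(all(res$note == "insufficient_pairs"))
  expect_true(all(is.na(res$p_adj)))
})

test_that("manipulation check recovers the configured rating structure", {
  cfg <- small_config(seed = 31, n_subjects = 38)
  sched <- default_study_schedule()
  ratings <- dplyr::bind_rows(lapply(seq_len(38), function(i) {
    id <- sprintf("s%02d", i)
    sess_sched <- dplyr::mutate(sched, subject_id = id)
    rm <- cfg$effect$rating_model
    set.seed(subject_seed(cfg$seed, i))
    idx <- match(sess_sched$category, rm$category)
    tibble::tibble(
      subject_id = id, video_id = sess_sched$video_id,
      valence = faceemg:::draw_ratings(25, rm$valence_mean[idx], rm$valence_sd[idx]),
      arousal = faceemg:::draw_ratings(25, rm$arousal_mean[idx], rm$arousal_sd[idx])
    )
  }))
  mc <- manipulation_check(ratings, sched)
  expect_equal(mc$n_subjects, 38)
  model <- default_rating_model()
  for (i in seq_len(nrow(model))) {
    row <- mc$summary[mc$summary$category == model$category[i], ]
    expect_lt(abs(row$valence_mean - model$valence_mean[i]), 0.5)
    expect_lt(abs(row$arousal_mean - model$arousal_mean[i]), 0.5)
  }
  # the configured separation is strong: omnibus tests fire and follow-ups run
  expect_lt(mc$friedman$valence$p, 0.001)
  expect_lt(mc$friedman$arousal$p, 0.001)
  expect_equal(nrow(mc$pairwise), 6L)
  # positive rated above negative on valence; negative most arousing
  pw <- mc$pairwise
  expect_gt(pw$z[pw$scale == "valence" & pw$contrast == "positive vs negative"], 0)
  expect_gt(pw$z[pw$scale == "arousal" & pw$contrast == "negative vs neutral"], 0)

  # identical ratings: omnibus chi2 is 0, nothing to follow up
  flat <- dplyr::mutate(ratings, valence = 5L, arousal = 5L)
  mc <- manipulation_check(flat, sched)
  expect_equal(mc$friedman$valence$chi2, 0)
  expect_equal(nrow(mc$pairwise), 0L)
})

test_that("segmented Pearson correlation matches the textbook formula", {
  lv <- rep(5:9, each = 4)
  vals <- 0.1 * lv + 0.02
  expect_equal(segment_pearson(lv, vals, 5, 9)$r, 1)

  set.seed(24)
  lv <- rep(1:9, each = 5)
  vals <- stats::runif(length(lv))
  res <- segment_pearson(lv, vals, 1, 5)
  keep <- lv <= 5
  x <- lv[keep]; y <- vals[keep]
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_manual, tolerance = 1e-12)
  expect_equal(res$n, sum(keep))
  tstat <- r_manual * sqrt((res$n - 2) / (1 - r_manual^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tstat), res$n - 2), tolerance = 1e-12)

  expect_error(segment_pearson(rep(5, 10), stats::runif(10), 1, 9),
               class = "faceemg_validation_error")
  expect_error(segment_pearson(1:2, 1:2, 1, 9), class = "faceemg_validation_error")
})

test_that("quadratic trends interpolate parabolas and recover noisy curvature", {
  lv <- rep(1:9, times = 2)
  fit <- quadratic_trend(lv, (lv - 5)^2)
  expect_equal(unname(fit$coefficients),
               c(25, -10, 1), tolerance = 1e-9)

  fit <- quadratic_trend(lv, 3 * lv + 1)
  expect_lt(abs(fit$coefficients["quadratic"]), 1e-9)

  set.seed(25)
  lv <- rep(1:9, length.out = 200)
  curv <- 0.03
  vals <- curv * (lv - 5)^2 + stats::rnorm(200, sd = 0.05)
  fit <- quadratic_trend(lv, vals)
  se <- tidy(fit)$std.error[3]
  expect_lt(abs(fit$coefficients["quadratic"] - curv), 3 * se)

  band <- trend_confidence_band(fit, levels = 1:9)
  expect_true(all(band$lwr <= band$fit & band$fit <= band$upr))

  expect_error(quadratic_trend(c(1, 1, 2, 2), c(1, 2, 3, 4)),
               class = "faceemg_validation_error")
})
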