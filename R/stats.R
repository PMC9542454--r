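#' Friedman rank test across within-subject conditions
#'
#' Nonparametric repeated-measures omnibus test: each subject's k condition
#' values are mid-ranked within subject; the chi-square statistic (with the
#' standard tie correction) tests whether the k mean ranks differ.
#'
#' @param x Numeric matrix or data frame, rows = subjects, columns =
#'   conditions; no missing cells.
#' @return An object of class `faceemg_friedman` with fields `chi2`, `df`,
#'   `p`, `mean_ranks`, `n`, `k`.
#' @export
#' @examples
#' m <- cbind(neutral = c(4, 5, 5), negative = c(3, 2, 4), positive = c(7, 6, 8))
#' friedman_rank_test(m)
friedman_rank_test <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    rlang::abort("Friedman test requires complete data (no missing cells).",
                 class = "faceemg_validation_error")
  }
  n <- nrow(x); k <- ncol(x)
  if (n < 2 || k < 2) {
    rlang::abort("Need at least 2 subjects and 2 conditions.",
                 class = "faceemg_validation_error")
  }
  ranks <- t(apply(x, 1, rank))           # within-subject mid-ranks
  rank_sums <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(rank_sums^2) - 3 * n * (k + 1)
  # tie correction: 1 - sum over subjects of (t^3 - t) / (n k (k^2 - 1))
  tie_term <- sum(apply(x, 1, function(row) {
    t_g <- table(row)
    sum(t_g^3 - t_g)
  }))
  C <- 1 - tie_term / (n * k * (k^2 - 1))
  chi2 <- if (C > 0) stat / C else 0
  df <- k - 1
  structure(
    list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE),
         mean_ranks = colMeans(ranks), n = n, k = k),
    class = "faceemg_friedman"
  )
}

#' @export
print.faceemg_friedman <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi2(%d) = %.3f, p = %.4g (n = %d)\n",
              x$df, x$chi2, x$p, x$n))
  cat("  mean ranks:", paste(sprintf("%s=%.2f",
                                     names(x$mean_ranks), x$mean_ranks),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Tests whether the paired differences `x - y` are symmetric about zero.
#' Zero differences are discarded by default (`zero_method = "pratt"` keeps
#' them in the ranking but drops their ranks from the sums). The p-value uses
#' the exact signed-rank distribution when there are no ties among the
#' non-zero absolute differences and at most 25 pairs remain, and the normal
#' approximation with tie-corrected variance (no continuity correction)
#' otherwise. The reported `z` always comes from the normal approximation and
#' is positive when `x` tends to exceed `y`.
#'
#' @param x,y Equal-length numeric vectors of paired observations.
#' @param zero_method `"discard"` (default) or `"pratt"`.
#' @param exact Force (`TRUE`)/suppress (`FALSE`) the exact p-value; default
#'   `NULL` chooses automatically as described.
#' @return An object of class `faceemg_wilcoxon` with fields `n_pairs`
#'   (after zero handling), `statistic` (signed-rank sum W+), `z`, `p`,
#'   `method`.
#' @export
#' @examples
#' wilcoxon_signed_rank(c(5, 7, 3, 9, 8, 6), c(2, 4, 4, 5, 3, 1))
wilcoxon_signed_rank <- function(x, y, zero_method = c("discard", "pratt"),
                                 exact = NULL) {
  zero_method <- match.arg(zero_method)
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[is.finite(d)]
  if (all(d == 0)) {
    rlang::abort("All paired differences are zero: degenerate comparison.",
                 class = "faceemg_degenerate_comparison")
  }
  if (zero_method == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
    n <- length(d)
    w_plus <- sum(r[d > 0])
    mu <- n * (n + 1) / 4
    ties <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  } else {
    r <- rank(abs(d))
    n_nonzero <- sum(d != 0)
    w_plus <- sum(r[d > 0])
    n0 <- sum(d == 0)
    n <- n_nonzero
    # Pratt: ranks of zeros removed from both the statistic and the moments
    N <- length(d)
    mu <- (N * (N + 1) - n0 * (n0 + 1)) / 4
    ties <- table(abs(d[d != 0]))
    sigma2 <- (N * (N + 1) * (2 * N + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24 -
      sum(ties^3 - ties) / 48
  }
  if (n < 5) {
    rlang::abort("Fewer than 5 non-zero paired differences.",
                 class = "faceemg_degenerate_comparison")
  }
  z <- (w_plus - mu) / sqrt(sigma2)
  has_ties <- anyDuplicated(abs(d[d != 0])) > 0
  use_exact <- if (is.null(exact)) {
    !has_ties && zero_method == "discard" && n <= 25
  } else {
    exact
  }
  if (use_exact && !has_ties && zero_method == "discard") {
    p <- if (w_plus > mu) {
      2 * stats::psignrank(w_plus - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(w_plus, n)
    }
    p <- min(1, p)
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  structure(
    list(n_pairs = n, statistic = w_plus, z = z, p = p, method = method,
         zero_method = zero_method),
    class = "faceemg_wilcoxon"
  )
}

#' @export
print.faceemg_wilcoxon <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W+ = %g, z = %.3f, p = %.4g (%s, n = %d)\n",
              x$statistic, x$z, x$p, x$method, x$n_pairs))
  invisible(x)
}

#' Bonferroni familywise correction
#'
#' @param p_raw Numeric vector of raw p-values in `[0, 1]`.
#' @param m Number of tests in the family (>= 1).
#' @return `min(1, m * p_raw)`, elementwise.
#' @export
#' @examples
#' bonferroni_adjust(c(0.01, 0.3), m = 6)
bonferroni_adjust <- function(p_raw, m) {
  stopifnot(m >= 1, all(p_raw >= 0 & p_raw <= 1, na.rm = TRUE))
  pmin(1, m * p_raw)
}

#' Star annotation of an (adjusted) p-value
#'
#' `ns` for p > 0.05, `*` for p in (0.01, 0.05], `**` for (0.001, 0.01],
#' `***` for (1e-4, 1e-3], `****` for p <= 1e-4.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of annotations.
#' @export
#' @examples
#' p_stars(c(0.5, 0.03, 0.005, 5e-4, 5e-5))
p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p > 0.05 ~ "ns",
    p > 0.01 ~ "*",
    p > 0.001 ~ "**",
    p > 1e-4 ~ "***",
    TRUE ~ "****"
  )
}

# Contrast definitions per scheme: each row is (x condition, y condition);
# the test operand order is x minus y.
scheme_contrasts <- function(scheme) {
  switch(scheme,
    valence_bin = list(c("V_negative", "V_positive")),
    arousal_bin = list(c("A_low", "A_high")),
    video_type = list(c("W_neutral", "W_positive"),
                      c("W_neutral", "W_negative"),
                      c("W_positive", "W_negative")),
    rlang::abort(paste0("No paired contrasts defined for scheme '", scheme, "'."),
                 class = "faceemg_validation_error")
  )
}

analysis_channels <- function() c(emg_channels(), sensor_average_label())

#' Paired amplitude comparisons with Bonferroni correction
#'
#' Runs the family of paired Wilcoxon signed-rank tests for one aggregation
#' scheme: one test per sensing modality (five sensors plus their average)
#' per condition contrast. The rating-bin schemes compare negative vs
#' positive valence (or low vs high arousal), a family of m = 6 tests; the
#' video-type scheme compares the three category pairs, a family of m = 18
#' tests. Subjects missing either member of a contrast are dropped pairwise.
#' Cells with fewer than 5 complete pairs, or with all-zero differences, are
#' reported with `NA` statistics and an explanatory `note`.
#'
#' @param means Condition means from [condition_means()].
#' @param scheme `"valence_bin"`, `"arousal_bin"` or `"video_type"`; defaults
#'   to the scheme recorded in `means`.
#' @param m Family size for the Bonferroni correction; defaults to the number
#'   of tests in the family (6 or 18).
#' @param zero_method Passed to [wilcoxon_signed_rank()].
#' @return Tibble with one row per test: `scheme`, `channel`, `contrast`,
#'   `x`, `y`, `n_pairs`, `statistic`, `z`, `p_raw`, `m`, `p_adj`,
#'   `annotation`, `note`.
#' @export
paired_amplitude_analysis <- function(means, scheme = NULL, m = NULL,
                                      zero_method = "discard") {
  stopifnot(is.data.frame(means),
            all(c("subject_id", "channel", "scheme", "condition", "value")
                %in% names(means)))
  if (is.null(scheme)) scheme <- unique(means$scheme)
  stopifnot(length(scheme) == 1)
  contrasts <- scheme_contrasts(scheme)
  chans <- intersect(analysis_channels(), unique(means$channel))
  if (is.null(m)) m <- length(contrasts) * length(chans)

  wide <- tidyr::pivot_wider(
    dplyr::filter(means, .data$scheme == !!scheme),
    id_cols = c("subject_id", "channel"),
    names_from = "condition", values_from = "value"
  )

  rows <- list()
  for (ch in chans) {
    for (ct in contrasts) {
      dat <- dplyr::filter(wide, .data$channel == ch)
      xv <- dat[[ct[1]]]; yv <- dat[[ct[2]]]
      if (is.null(xv)) xv <- rep(NA_real_, nrow(dat))
      if (is.null(yv)) yv <- rep(NA_real_, nrow(dat))
      ok <- is.finite(xv) & is.finite(yv)
      res <- tibble::tibble(
        scheme = scheme, channel = ch,
        contrast = paste(ct[1], "vs", ct[2]), x = ct[1], y = ct[2],
        n_pairs = sum(ok), statistic = NA_real_, z = NA_real_,
        p_raw = NA_real_, m = m, p_adj = NA_real_,
        annotation = NA_character_, note = NA_character_
      )
      if (sum(ok) < 5) {
        res$note <- "insufficient_pairs"
      } else {
        w <- tryCatch(
          wilcoxon_signed_rank(xv[ok], yv[ok], zero_method = zero_method),
          faceemg_degenerate_comparison = function(e) NULL
        )
        if (is.null(w)) {
          res$note <- "degenerate_comparison"
        } else {
          res$n_pairs <- w$n_pairs
          res$statistic <- w$statistic
          res$z <- w$z
          res$p_raw <- w$p
          res$p_adj <- bonferroni_adjust(w$p, m)
          res$annotation <- p_stars(res$p_adj)
        }
      }
      rows[[length(rows) + 1L]] <- res
    }
  }
  dplyr::bind_rows(rows)
}

#' Manipulation check on the self-reports
#'
#' Verifies that the stimulus categories induced the intended affect:
#' per-category mean and SD of valence and arousal (computed over the
#' per-subject per-category means), a Friedman omnibus test across the three
#' categories per scale, and - when the omnibus test is significant at 0.05 -
#' the three pairwise Wilcoxon follow-ups per scale (uncorrected p-values;
#' the z sign is positive when the first-named category's ratings exceed the
#' second's).
#'
#' @param ratings Ratings tibble covering all subjects.
#' @param schedule Schedule tibble mapping `video_id` to `category` (one
#'   subject's schedule suffices when all subjects share it).
#' @return An object of class `faceemg_manipulation_check`: a list with
#'   `summary` (per-category means/SDs), `friedman` (per scale),
#'   `pairwise` (tibble), `n_subjects`.
#' @export
manipulation_check <- function(ratings, schedule) {
  ratings <- validate_ratings(ratings)
  schedule <- validate_schedule(schedule)
  cat_map <- dplyr::distinct(schedule, .data$video_id, .data$category)
  dat <- dplyr::inner_join(ratings, cat_map, by = "video_id")
  if (nrow(dat) < nrow(ratings)) {
    rlang::abort("Some rated videos have no category in the schedule.",
                 class = "faceemg_validation_error")
  }
  per_subj <- dat |>
    dplyr::group_by(.data$subject_id, .data$category) |>
    dplyr::summarise(valence = mean(.data$valence), arousal = mean(.data$arousal),
                     .groups = "drop")

  complete <- per_subj |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == length(video_categories()))
  if (nrow(complete) < length(unique(per_subj$subject_id))) {
    rlang::warn("Subject(s) missing a category were dropped from the manipulation check.",
                class = "faceemg_missing_condition")
  }
  per_subj <- dplyr::semi_join(per_subj, complete, by = "subject_id")

  summary_tbl <- per_subj |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      valence_mean = mean(.data$valence), valence_sd = stats::sd(.data$valence),
      arousal_mean = mean(.data$arousal), arousal_sd = stats::sd(.data$arousal),
      .groups = "drop"
    ) |>
    dplyr::arrange(factor(.data$category, levels = video_categories()))

  pairs <- list(c("negative", "neutral"), c("positive", "negative"),
                c("positive", "neutral"))
  friedman <- list()
  pairwise <- list()
  for (scale in c("valence", "arousal")) {
    wide <- tidyr::pivot_wider(per_subj[c("subject_id", "category", scale)],
                               names_from = "category",
                               values_from = dplyr::all_of(scale))
    mat <- as.matrix(wide[video_categories()])
    fr <- friedman_rank_test(mat)
    friedman[[scale]] <- fr
    if (fr$p < 0.05) {
      for (pr in pairs) {
        w <- tryCatch(
          wilcoxon_signed_rank(wide[[pr[1]]], wide[[pr[2]]]),
          faceemg_degenerate_comparison = function(e) NULL
        )
        pairwise[[length(pairwise) + 1L]] <- tibble::tibble(
          scale = scale, contrast = paste(pr[1], "vs", pr[2]),
          n_pairs = if (is.null(w)) NA_integer_ else w$n_pairs,
          z = if (is.null(w)) NA_real_ else w$z,
          p = if (is.null(w)) NA_real_ else w$p,
          annotation = if (is.null(w)) NA_character_ else p_stars(w$p)
        )
      }
    }
  }
  structure(
    list(summary = summary_tbl, friedman = friedman,
         pairwise = dplyr::bind_rows(pairwise),
         n_subjects = nrow(complete)),
    class = "faceemg_manipulation_check"
  )
}

#' @export
print.faceemg_manipulation_check <- function(x, ...) {
  cat(sprintf("Manipulation check (n = %d subjects)\n", x$n_subjects))
  cat("Per-category self-reports (mean +/- SD over per-subject means):\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s valence %.2f +/- %.2f   arousal %.2f +/- %.2f\n",
                s$category[i], s$valence_mean[i], s$valence_sd[i],
                s$arousal_mean[i], s$arousal_sd[i]))
  }
  for (scale in names(x$friedman)) {
    f <- x$friedman[[scale]]
    cat(sprintf("%s: Friedman chi2(%d) = %.2f, p = %.3g; mean ranks %s\n",
                scale, f$df, f$chi2, f$p,
                paste(sprintf("%s=%.2f", names(f$mean_ranks), f$mean_ranks),
                      collapse = ", ")))
  }
  if (nrow(x$pairwise) > 0) {
    cat("Pairwise Wilcoxon follow-ups (uncorrected):\n")
    pw <- x$pairwise
    for (i in seq_len(nrow(pw))) {
      cat(sprintf("  %-8s %-22s z = %6.3f, p = %.3g %s\n", pw$scale[i],
                  pw$contrast[i], pw$z[i], pw$p[i], pw$annotation[i]))
    }
  }
  invisible(x)
}

#' Pearson correlation over a rating-level segment
#'
#' Correlates per-subject-per-level mean amplitudes with the rating level
#' over an inclusive level range, e.g. `[1, 5]` for the negative-to-neutral
#' limb of the V-shape and `[5, 9]` for the neutral-to-positive limb.
#'
#' @param levels Numeric vector of rating levels (1-9).
#' @param values Numeric vector of mean amplitudes, same length.
#' @param lo,hi Inclusive bounds of the segment.
#' @return One-row tibble: `lo`, `hi`, `r`, `p`, `n`.
#' @export
segment_pearson <- function(levels, values, lo, hi) {
  stopifnot(length(levels) == length(values))
  keep <- is.finite(levels) & is.finite(values) & levels >= lo & levels <= hi
  x <- levels[keep]; y <- values[keep]
  if (length(x) < 3) {
    rlang::abort("Need at least 3 points in the segment.",
                 class = "faceemg_validation_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("Zero variance in the segment: correlation undefined.",
                 class = "faceemg_validation_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(lo = lo, hi = hi, r = unname(ct$estimate), p = ct$p.value,
                 n = length(x))
}

#' Quadratic trend of amplitude against rating level
#'
#' Ordinary least-squares fit of `value ~ level + level^2`. A positive
#' quadratic coefficient indicates the V/U-shaped relation between amplitude
#' and valence reported for the "positive" muscles.
#'
#' @param levels Numeric rating levels.
#' @param values Numeric amplitudes, same length.
#' @return An object of class `faceemg_trend` wrapping the `lm` fit, with
#'   `coefficients` named `intercept`, `linear`, `quadratic`.
#' @export
#' @examples
#' lv <- rep(1:9, each = 3)
#' quadratic_trend(lv, (lv - 5)^2)
quadratic_trend <- function(levels, values) {
  stopifnot(length(levels) == length(values))
  keep <- is.finite(levels) & is.finite(values)
  levels <- levels[keep]; values <- values[keep]
  if (length(levels) < 4) {
    rlang::abort("Need at least 4 points.", class = "faceemg_validation_error")
  }
  if (length(unique(levels)) < 3) {
    rlang::abort("Need at least 3 distinct levels (quadratic fit is rank-deficient).",
                 class = "faceemg_validation_error")
  }
  dat <- data.frame(level = levels, value = values)
  fit <- stats::lm(value ~ level + I(level^2), data = dat)
  co <- stats::coef(fit)
  structure(
    list(model = fit,
         coefficients = c(intercept = unname(co[1]), linear = unname(co[2]),
                          quadratic = unname(co[3])),
         n = length(levels)),
    class = "faceemg_trend"
  )
}

#' @export
print.faceemg_trend <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "Quadratic trend (n = %d): value = %.4f %+.4f * level %+.4f * level^2 (%s-shaped)\n",
    x$n, co["intercept"], co["linear"], co["quadratic"],
    if (co["quadratic"] > 0) "V/U" else "inverted-U"
  ))
  invisible(x)
}

#' 95% confidence band of a fitted quadratic trend
#'
#' @param trend A [quadratic_trend()] fit.
#' @param levels Levels at which to evaluate the band (default a fine grid
#'   over the fitted range).
#' @return Tibble `level`, `fit`, `lwr`, `upr`.
#' @export
trend_confidence_band <- function(trend, levels = NULL) {
  stopifnot(inherits(trend, "faceemg_trend"))
  if (is.null(levels)) {
    rng <- range(trend$model$model$level)
    levels <- seq(rng[1], rng[2], length.out = 100)
  }
  pr <- stats::predict(trend$model, newdata = data.frame(level = levels),
                       interval = "confidence", level = 0.95)
  tibble::tibble(level = levels, fit = pr[, "fit"], lwr = pr[, "lwr"],
                 upr = pr[, "upr"])
}
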