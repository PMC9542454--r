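#' Plot a session's normalized envelopes
#'
#' One line per channel over the session, with the video events shaded by
#' category - the standard at-a-glance view of a recording.
#'
#' @param env Long normalized envelope tibble (see [session_envelopes()]).
#' @param schedule Optional schedule tibble for category shading.
#' @return A ggplot object.
#' @export
plot_session_envelopes <- function(env, schedule = NULL) {
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$time_s, y = .data$amplitude))
  if (!is.null(schedule)) {
    p <- p + ggplot2::geom_rect(
      data = schedule,
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$category),
      alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(values = c(neutral = "grey50",
                                            negative = "#c0392b",
                                            positive = "#27ae60"))
  }
  p +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = "normalized amplitude") +
    ggplot2::theme_minimal()
}

#' Boxplots of per-subject condition means
#'
#' The field's standard summary figure: one panel per sensing modality,
#' boxplots of the per-subject mean normalized amplitude per condition.
#'
#' @param means Condition means tibble from [condition_means()].
#' @return A ggplot object.
#' @export
plot_condition_means <- function(means) {
  ggplot2::ggplot(means, ggplot2::aes(x = .data$condition, y = .data$value,
                                      fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = NULL, y = "mean normalized amplitude") +
    ggplot2::theme_minimal()
}

#' Amplitude-versus-valence scatterplot with the quadratic trend
#'
#' Reproduces the V-shape diagnostic: per-subject-per-level mean amplitudes
#' against valence level, the fitted second-order regression line, and its
#' 95% confidence band.
#'
#' @param object A `faceemg_trend` fit from [quadratic_trend()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.faceemg_trend <- function(object, ...) {
  band <- trend_confidence_band(object)
  dat <- object$model$model
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_ribbon(data = band,
                         ggplot2::aes(x = .data$level, ymin = .data$lwr,
                                      ymax = .data$upr),
                         alpha = 0.2, inherit.aes = FALSE) +
    ggplot2::geom_line(data = band,
                       ggplot2::aes(x = .data$level, y = .data$fit),
                       colour = "#2c3e50", inherit.aes = FALSE) +
    ggplot2::geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::labs(x = "valence level", y = "mean normalized amplitude") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
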