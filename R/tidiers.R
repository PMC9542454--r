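#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Friedman rank test
#' @param x A `faceemg_friedman` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `df`, `p.value`, `n`, `method`.
#' @export
tidy.faceemg_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p, n = x$n,
                 method = "Friedman rank test")
}

#' @rdname tidy.faceemg_friedman
#' @export
glance.faceemg_friedman <- function(x, ...) tidy(x)

#' Tidy a Wilcoxon signed-rank test
#' @param x A `faceemg_wilcoxon` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic` (W+), `z`, `p.value`, `n`,
#'   `method`.
#' @export
tidy.faceemg_wilcoxon <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, z = x$z, p.value = x$p,
                 n = x$n_pairs,
                 method = paste0("Wilcoxon signed-rank (", x$method, ")"))
}

#' Tidy a quadratic trend fit
#' @param x A `faceemg_trend` object.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @export
tidy.faceemg_trend <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "linear", "quadratic"),
    estimate = s[, 1], std.error = s[, 2], statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname tidy.faceemg_trend
#' @export
glance.faceemg_trend <- function(x, ...) {
  s <- summary(x$model)
  tibble::tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
                 sigma = s$sigma, n = x$n)
}
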