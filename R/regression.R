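# Linear regression of a movement metric on transmission period, the
# inferential step of the thinning sensitivity analysis.

#' Regress a movement metric on transmission period
#'
#' Ordinary least squares of a (optionally log10-transformed) movement
#' metric on transmission period, pooling all fish-by-period points.
#' With five fish and seven datasets each this is a 35-point fit with 33
#' residual degrees of freedom.
#'
#' @param data A data frame of one point per fish-by-period dataset.
#' @param metric Column holding the metric value (tidy-eval).
#' @param period Column holding the transmission period, s (tidy-eval;
#'   default `transmission_period_s`).
#' @param transform `"none"` or `"log10"` (metric must be positive).
#' @return An object of class `period_fit` wrapping the [stats::lm()]
#'   fit; see [tidy.period_fit()], [glance.period_fit()],
#'   [autoplot.period_fit()].
#' @examples
#' pts <- tibble::tibble(transmission_period_s = rep(c(4, 7, 10, 15, 30, 45, 60), 2),
#'                       distance_m = 10^(2.14 - 0.01 * rep(c(4, 7, 10, 15, 30, 45, 60), 2)))
#' fit <- metric_period_regression(pts, distance_m, transform = "log10")
#' glance(fit)
#' @export
metric_period_regression <- function(data, metric, period = NULL,
                                     transform = c("none", "log10")) {
  stopifnot(is.data.frame(data))
  transform <- match.arg(transform)
  y <- rlang::eval_tidy(rlang::enquo(metric), data)
  pq <- rlang::enquo(period)
  x <- if (rlang::quo_is_null(pq)) data[["transmission_period_s"]] else
    rlang::eval_tidy(pq, data)
  if (is.null(x)) stop("no `transmission_period_s` column and no `period` given", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 points for regression", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in period", call. = FALSE)
  if (transform == "log10") {
    if (any(y <= 0)) stop("metric must be positive for log10 transform", call. = FALSE)
    y <- log10(y)
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  structure(list(fit = fit, transform = transform, n = length(x)),
            class = "period_fit")
}

#' @export
print.period_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<period_fit> %s metric ~ period: y = %+0.4g x %+0.4g\n  F(%d, %d) = %.3g, p = %.3g, r^2 = %.3g, n = %d\n",
    x$transform, g$slope, g$intercept, g$df1, g$df2, g$F, g$p_value, g$r_squared, g$n))
  invisible(x)
}

#' Tidy a period regression fit
#'
#' @param x A `period_fit` from [metric_period_regression()].
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`.
#' @method tidy period_fit
#' @export
tidy.period_fit <- function(x, ...) {
  co <- stats::coef(summary(x$fit))
  tibble::tibble(
    term = c("intercept", "period"),
    estimate = unname(co[, 1]), std_error = unname(co[, 2]),
    statistic = unname(co[, 3]), p_value = unname(co[, 4])
  )
}

#' Model-level summary of a period regression fit
#'
#' @inheritParams tidy.period_fit
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `F`,
#'   `df1`, `df2`, `p_value`, `transform`, `n`.
#' @method glance period_fit
#' @export
glance.period_fit <- function(x, ...) {
  s <- summary(x$fit)
  fs <- s$fstatistic
  tibble::tibble(
    slope = unname(stats::coef(x$fit)[2]),
    intercept = unname(stats::coef(x$fit)[1]),
    r_squared = s$r.squared,
    F = unname(fs[1]), df1 = as.integer(fs[2]), df2 = as.integer(fs[3]),
    p_value = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    transform = x$transform,
    n = x$n
  )
}
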