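# Movement metrics computed from a positional track: total distance
# travelled, per-step speed, and unsigned turning angle.

#' Movement metrics of a track
#'
#' Step lengths are Euclidean distances between consecutive fixes; speed
#' is step length over step duration; the turning angle at an interior
#' fix is the unsigned angle (degrees, 0 = straight ahead, up to 180)
#' between the incoming and outgoing displacement vectors. A vertex
#' adjacent to a zero-length step has no defined turning angle; such
#' vertices are skipped and counted in `n_degenerate`.
#'
#' @param track Fix table (`time_s`, `x_m`, `y_m`) with strictly
#'   increasing times. Fewer than 2 fixes give zero distance and empty
#'   summaries; fewer than 3 give no turning angles.
#' @return One-row tibble: `n_fixes`, `n_steps`, `total_distance_m`,
#'   `speed_mean`, `speed_median`, `speed_p5`, `speed_p95`,
#'   `angle_mean`, `angle_median`, `angle_p5`, `angle_p95`,
#'   `n_degenerate`. The per-step speeds and per-vertex angles are kept
#'   in the `"speeds"` and `"angles"` attributes.
#' @examples
#' tr <- tibble::tibble(time_s = 0:2, x_m = c(0, 1, 1), y_m = c(0, 0, 1))
#' movement_metrics(tr) # distance 2, speeds 1, turning angle 90
#' @export
movement_metrics <- function(track) {
  stopifnot(is.data.frame(track))
  check_track(track, min_fixes = 0)
  n <- nrow(track)
  if (n >= 2 && is.unsorted(track$time_s, strictly = TRUE)) {
    stop("track times must be strictly increasing", call. = FALSE)
  }
  if (n < 2) {
    return(metrics_row(n, numeric(), numeric(), numeric(), 0L))
  }
  dx <- diff(track$x_m)
  dy <- diff(track$y_m)
  dt <- diff(track$time_s)
  step <- sqrt(dx^2 + dy^2)
  speeds <- step / dt
  angles <- numeric()
  n_degen <- 0L
  if (n >= 3) {
    i <- seq_len(n - 2)
    ok <- step[i] > 0 & step[i + 1] > 0
    n_degen <- sum(!ok)
    dot <- dx[i] * dx[i + 1] + dy[i] * dy[i + 1]
    cosang <- pmin(1, pmax(-1, dot / (step[i] * step[i + 1])))
    angles <- acos(cosang[ok]) * 180 / pi
  }
  metrics_row(n, step, speeds, angles, n_degen)
}

metrics_row <- function(n_fixes, steps, speeds, angles, n_degenerate) {
  qs <- function(v) {
    if (length(v) == 0) return(rep(NA_real_, 4))
    c(mean(v), stats::quantile(v, c(0.5, 0.05, 0.95), names = FALSE, type = 7))
  }
  sp <- qs(speeds)
  an <- qs(angles)
  out <- tibble::tibble(
    n_fixes = n_fixes, n_steps = length(steps),
    total_distance_m = sum(steps),
    speed_mean = sp[1], speed_median = sp[2], speed_p5 = sp[3], speed_p95 = sp[4],
    angle_mean = an[1], angle_median = an[2], angle_p5 = an[3], angle_p95 = an[4],
    n_degenerate = n_degenerate
  )
  attr(out, "speeds") <- speeds
  attr(out, "angles") <- angles
  out
}

#' Thinning sensitivity analysis of a track
#'
#' Thins a track to each requested minimum period and tabulates, for the
#' native track and each thinned version, the observed position-period
#' summary, the number of positions, and the movement metrics — showing
#' how distance travelled, speed and turning angle degrade as the
#' effective transmission period grows.
#'
#' @param track Fix table (`time_s`, `x_m`, `y_m`).
#' @param periods Minimum periods to thin to, s. Defaults to the
#'   ladder 7, 10, 15, 30, 45, 60 s.
#' @param native_period_s Nominal transmission period of the native
#'   track, s, used to label its row (default: its median observed
#'   position period).
#' @return A tibble of class `hr_sensitivity`, one row per dataset
#'   (native first): `dataset`, `transmission_period_s`,
#'   `position_period_median`, `position_period_min`,
#'   `position_period_max`, `n_positions`, `distance_m`,
#'   `speed_median`, `speed_p5`, `speed_p95`, `angle_median`,
#'   `angle_p5`, `angle_p95`.
#' @export
sensitivity_analysis <- function(track, periods = c(7, 10, 15, 30, 45, 60),
                                 native_period_s = NULL) {
  check_track(track, min_fixes = 2)
  stopifnot(all(periods > 0))
  if (is.null(native_period_s)) {
    native_period_s <- position_period_summary(track)$median_s
  }
  one_row <- function(tr, label, period) {
    pp <- if (nrow(tr) >= 2) position_period_summary(tr) else
      tibble::tibble(median_s = NA_real_, min_s = NA_real_, max_s = NA_real_)
    mm <- movement_metrics(tr)
    tibble::tibble(
      dataset = label,
      transmission_period_s = period,
      position_period_median = pp$median_s,
      position_period_min = pp$min_s,
      position_period_max = pp$max_s,
      n_positions = nrow(tr),
      distance_m = mm$total_distance_m,
      speed_median = mm$speed_median, speed_p5 = mm$speed_p5, speed_p95 = mm$speed_p95,
      angle_median = mm$angle_median, angle_p5 = mm$angle_p5, angle_p95 = mm$angle_p95
    )
  }
  out <- dplyr::bind_rows(
    one_row(track, "native", native_period_s),
    purrr::map_dfr(sort(periods), function(p) {
      one_row(thin_track(track, p), sprintf("thinned_%g", p), p)
    })
  )
  class(out) <- c("hr_sensitivity", class(out))
  out
}
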