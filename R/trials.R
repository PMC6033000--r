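# Trial evaluation: accuracy (distance to an independent GPS reference)
# and precision (distance to the trial's own median position), each
# summarised as median [5th–95th percentile] and range.

#' Summarise a set of per-fix distances
#'
#' The common summary used for every accuracy and precision measure:
#' median, 5th and 95th percentiles (linear interpolation between
#' closest ranks), and range.
#'
#' @param values Non-empty numeric vector of distances, m.
#' @param duration_s Optional trial duration to carry through, s.
#' @return One-row tibble: `n`, `median_m`, `p5_m`, `p95_m`, `min_m`,
#'   `max_m`, `duration_s`. The raw distances are kept in the
#'   `"distances"` attribute.
#' @export
trial_stats <- function(values, duration_s = NA_real_) {
  if (length(values) == 0) stop("no distances to summarise", call. = FALSE)
  stopifnot(all(is.finite(values)))
  q <- stats::quantile(values, c(0.05, 0.5, 0.95), names = FALSE, type = 7)
  out <- tibble::tibble(
    n = length(values),
    median_m = q[2], p5_m = q[1], p95_m = q[3],
    min_m = min(values), max_m = max(values),
    duration_s = duration_s
  )
  attr(out, "distances") <- values
  out
}

check_track <- function(track, min_fixes = 1) {
  stopifnot(is.data.frame(track))
  need <- c("time_s", "x_m", "y_m")
  if (!all(need %in% names(track))) {
    stop("track needs columns `time_s`, `x_m`, `y_m`", call. = FALSE)
  }
  if (nrow(track) < min_fixes) {
    stop(sprintf("track needs at least %d fix(es)", min_fixes), call. = FALSE)
  }
  invisible(track)
}

track_duration <- function(track) {
  if (nrow(track) < 2) return(NA_real_)
  diff(range(track$time_s))
}

#' Accuracy of a stationary trial
#'
#' Distance of each estimated position from the known (GPS-recorded)
#' deployment position, summarised with [trial_stats()].
#'
#' @param track Fix table for one trial (`time_s`, `x_m`, `y_m`).
#' @param ref Reference position `c(x, y)`, m.
#' @return One-row tibble of summary statistics (see [trial_stats()]).
#' @export
accuracy_stationary <- function(track, ref) {
  check_track(track)
  stopifnot(length(ref) == 2, all(is.finite(ref)))
  d <- plane_distance(track$x_m, track$y_m, ref[1], ref[2])
  trial_stats(d, track_duration(track))
}

#' Precision of a stationary trial
#'
#' Distance of each estimated position from the coordinate-wise median
#' of all positions in the trial — a measure of scatter that is blind to
#' any constant bias against the true location.
#'
#' @inheritParams accuracy_stationary
#' @return One-row tibble of summary statistics; the median position is
#'   stored in the `"median_position"` attribute.
#' @export
precision_stationary <- function(track) {
  check_track(track)
  mx <- stats::median(track$x_m)
  my <- stats::median(track$y_m)
  out <- trial_stats(plane_distance(track$x_m, track$y_m, mx, my),
                     track_duration(track))
  attr(out, "median_position") <- c(x_m = mx, y_m = my)
  out
}

#' Accuracy of a moving trial against a GPS track
#'
#' Each fix is compared with the GPS position time-matched to it by
#' linear interpolation of the (nominally 1 Hz) GPS track. Fixes up to
#' `edge_tol_s` outside the GPS time span are matched to the nearest
#' endpoint; fixes farther outside are dropped and counted.
#'
#' @inheritParams accuracy_stationary
#' @param gps GPS reference track (`time_s`, `x_m`, `y_m`).
#' @param edge_tol_s Tolerance for fixes just outside GPS coverage, s.
#' @return One-row tibble of summary statistics with an extra column
#'   `n_dropped` (fixes outside GPS coverage).
#' @export
accuracy_moving <- function(track, gps, edge_tol_s = 2) {
  check_track(track)
  check_track(gps, min_fixes = 2)
  rng <- range(gps$time_s)
  inside <- track$time_s >= rng[1] - edge_tol_s & track$time_s <= rng[2] + edge_tol_s
  n_dropped <- sum(!inside)
  kept <- track[inside, ]
  if (nrow(kept) == 0) stop("no temporal overlap between track and GPS record", call. = FALSE)
  t_match <- pmin(pmax(kept$time_s, rng[1]), rng[2])
  gx <- stats::approx(gps$time_s, gps$x_m, xout = t_match, ties = "ordered")$y
  gy <- stats::approx(gps$time_s, gps$y_m, xout = t_match, ties = "ordered")$y
  out <- trial_stats(plane_distance(kept$x_m, kept$y_m, gx, gy),
                     track_duration(kept))
  out$n_dropped <- n_dropped
  out
}
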