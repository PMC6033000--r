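# Track thinning: emulate a slower tag by removing fixes until every
# consecutive interval meets a minimum period.

#' Thin a track to a minimum position period
#'
#' Removes fixes so that all remaining consecutive intervals are at
#' least `min_period_s`, emulating a tag with a longer transmission
#' period. Implemented as a greedy forward scan — keep the first fix,
#' then keep each subsequent fix iff its gap from the last kept fix is
#' `>= min_period_s` — which is exactly equivalent to repeatedly
#' deleting the first (chronological) fix whose gap from its predecessor
#' is below the threshold and recomputing, and is idempotent.
#'
#' @param track Fix table with a `time_s` column (strictly increasing);
#'   any other columns are carried through.
#' @param min_period_s Minimum retained interval, s (> 0).
#' @return The retained subset of `track` (possibly empty input gives
#'   empty output).
#' @examples
#' tr <- tibble::tibble(time_s = 0:10)
#' thin_track(tr, 3)$time_s # 0, 3, 6, 9
#' @export
thin_track <- function(track, min_period_s) {
  stopifnot(is.data.frame(track), "time_s" %in% names(track),
            is.numeric(min_period_s), min_period_s > 0)
  n <- nrow(track)
  if (n == 0) return(track)
  t <- track$time_s
  if (is.unsorted(t, strictly = TRUE)) stop("track times must be strictly increasing", call. = FALSE)
  keep <- integer(n)
  k <- 1L
  keep[1] <- 1L
  i <- 1L
  repeat {
    cand <- which(t[(i + 1):n] >= t[i] + min_period_s)
    if (length(cand) == 0) break
    i <- i + cand[1]
    k <- k + 1L
    keep[k] <- i
  }
  track[keep[seq_len(k)], , drop = FALSE]
}

#' Summary of intervals between consecutive fixes
#'
#' The observed position period of a track: median and range of the
#' consecutive time differences. Because not every transmission yields a
#' position, the observed period of a field record sits at or above the
#' tag's transmission period.
#'
#' @param track Fix table with `time_s` (>= 2 fixes).
#' @return One-row tibble: `n_intervals`, `median_s`, `min_s`, `max_s`.
#' @export
position_period_summary <- function(track) {
  stopifnot(is.data.frame(track), "time_s" %in% names(track))
  if (nrow(track) < 2) stop("need at least 2 fixes to compute position periods", call. = FALSE)
  gaps <- diff(track$time_s)
  tibble::tibble(
    n_intervals = length(gaps),
    median_s = stats::median(gaps),
    min_s = min(gaps),
    max_s = max(gaps)
  )
}

#' Shortest possible positioning period of a pulse-train tag
#'
#' For coding schemes that transmit a pulse train, a new position can be
#' obtained at best every burst length plus transmission delay; e.g. a
#' 3 s burst with a 5 s delay cannot be positioned more often than every
#' 8 s.
#'
#' @param burst_s Burst (pulse-train) length, s (>= 0).
#' @param delay_s Delay between transmissions, s (>= 0).
#' @return Minimum positioning period, s.
#' @export
min_positioning_period <- function(burst_s, delay_s) {
  if (any(burst_s < 0) || any(delay_s < 0)) {
    stop("burst and delay must be non-negative", call. = FALSE)
  }
  burst_s + delay_s
}

#' Percent reduction in position count under thinning
#'
#' @param n_native Number of fixes in the native track (> 0).
#' @param n_thinned Number of fixes after thinning (<= `n_native`).
#' @return Percentage `100 * (1 - n_thinned / n_native)`.
#' @export
percent_reduction <- function(n_native, n_thinned) {
  stopifnot(n_native > 0)
  if (any(n_thinned > n_native)) {
    stop("thinned count cannot exceed native count", call. = FALSE)
  }
  100 * (1 - n_thinned / n_native)
}
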