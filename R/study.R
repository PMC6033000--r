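# Replicated thinning study on simulated fish fix sequences: the
# simulation counterpart of a multi-fish field record, used to
# characterise how the observed position period and position count
# respond to thinning.

#' Replicated thinning study on simulated fish records
#'
#' Simulates `n_fish` independent fix-time sequences per replicate
#' ([simulate_fix_times()]: 15-minute records with transmission gaps
#' uniform on `[period_min, period_max]` and a fraction `p_omit` of
#' fixes lost), thins each to every requested minimum period, and
#' summarises per replicate and threshold the median across fish of the
#' per-fish median retained gap, the median per-fish position count,
#' and the pooled percent reduction in positions relative to the native
#' sequences.
#'
#' @param n_replicates Number of replicate simulations.
#' @param n_fish Fish (independent sequences) per replicate.
#' @param thresholds Minimum periods to thin to, s.
#' @param duration_s,period_min,period_max,p_omit Passed to
#'   [simulate_fix_times()].
#' @return A tibble, one row per replicate-by-threshold:
#'   `replicate`, `min_period_s`, `median_period_s` (median across fish
#'   of per-fish median retained gap), `n_positions` (median across
#'   fish), `n_native` (median across fish of native counts),
#'   `pct_reduction` (pooled over fish).
#' @examples
#' set.seed(7)
#' thinning_study(n_replicates = 2, thresholds = c(7, 60))
#' @export
thinning_study <- function(n_replicates = 200, n_fish = 5,
                           thresholds = c(7, 15, 30, 45, 60),
                           duration_s = 900, period_min = 3, period_max = 5,
                           p_omit = 0.08) {
  stopifnot(n_replicates >= 1, n_fish >= 1, all(thresholds > 0))
  purrr::map_dfr(seq_len(n_replicates), function(rep) {
    fish <- purrr::map(seq_len(n_fish), function(f) {
      simulate_fix_times(duration_s, period_min, period_max, p_omit)
    })
    n_native <- vapply(fish, length, 0L)
    purrr::map_dfr(thresholds, function(thr) {
      thinned <- purrr::map(fish, function(t) {
        thin_track(tibble::tibble(time_s = t), thr)$time_s
      })
      med_gap <- vapply(thinned, function(t) stats::median(diff(t)), 0)
      n_thin <- vapply(thinned, length, 0L)
      pct <- percent_reduction(sum(n_native), sum(n_thin))
      tibble::tibble(
        replicate = rep,
        min_period_s = thr,
        median_period_s = stats::median(med_gap),
        n_positions = stats::median(n_thin),
        n_native = stats::median(n_native),
        pct_reduction = pct
      )
    })
  })
}
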