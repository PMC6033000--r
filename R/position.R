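# Two-dimensional TDOA positioning. Detections are clustered into
# transmissions, each 3-receiver subset is solved exactly (the pairwise
# differences of the range equations are linear in position given the
# emission time, which leaves a quadratic in the emission time), and the
# subset solutions are combined by a weighted mean that favours the
# subsets least sensitive to arrival-time error.

#' Group detections into transmissions
#'
#' Single-linkage clustering of arrival times per tag: two detections
#' belong to the same transmission if they are closer in time than the
#' maximum acoustic travel-time difference across the array plus a guard
#' interval. Within a group, only the earliest detection per receiver is
#' kept; groups seen by fewer than three distinct receivers cannot be
#' positioned and are discarded.
#'
#' @param detections Tibble with `receiver_id`, `tag_id`, `time_s`.
#' @param array Receiver table (`receiver_id`, `x_m`, `y_m`).
#' @param c_ms Sound speed, m/s.
#' @param guard_s Guard added to the travel-time window, s. The default
#'   0.05 s covers the sub-10-ms HR burst plus clock slack.
#' @return The detections that survive, with a `transmission` integer
#'   column identifying the group (unique within tag).
#' @export
group_transmissions <- function(detections, array, c_ms = 1447, guard_s = 0.05) {
  validate_array(array)
  stopifnot(is.data.frame(detections),
            all(c("receiver_id", "tag_id", "time_s") %in% names(detections)))
  d <- as.matrix(stats::dist(array[, c("x_m", "y_m")]))
  window <- max(d) / c_ms + guard_s
  detections |>
    dplyr::arrange(.data$tag_id, .data$time_s) |>
    dplyr::group_by(.data$tag_id) |>
    dplyr::mutate(transmission = cumsum(c(TRUE, diff(.data$time_s) > window))) |>
    dplyr::group_by(.data$tag_id, .data$transmission, .data$receiver_id) |>
    dplyr::slice_min(.data$time_s, n = 1, with_ties = FALSE) |>
    dplyr::group_by(.data$tag_id, .data$transmission) |>
    dplyr::filter(dplyr::n() >= 3) |>
    dplyr::ungroup()
}

#' Solve one three-receiver TDOA subset exactly
#'
#' Solves `|p - r_i| / c + t0 = a_i` (i = 1, 2, 3) for the tag position
#' `p = (x, y)` and emission time `t0`. Subtracting pairs of the squared
#' range equations gives two equations linear in `(x, y)` for given
#' `t0`; substituting back yields a quadratic in `t0`, so there are 0, 1
#' or 2 candidate solutions. Only roots with `t0` earlier than the first
#' arrival are physical and returned. On noise-free arrivals the true
#' position is recovered to well below 1e-6 m.
#'
#' @param rx,ry Receiver coordinates, length-3 numeric, m. Must be
#'   non-collinear (triangle area > 1e-6 m^2).
#' @param arrivals Arrival times at the three receivers, s.
#' @param c_ms Sound speed, m/s.
#' @return A tibble of candidate solutions with columns `x_m`, `y_m`,
#'   `t0_s`, `sensitivity` (see [tdoa_sensitivity()]); zero rows if no
#'   physical real root exists.
#' @examples
#' # equilateral triangle, equal arrival times: the tag must sit at the
#' # circumcenter
#' rx <- cos(c(90, 210, 330) * pi / 180) * 100
#' ry <- sin(c(90, 210, 330) * pi / 180) * 100
#' solve_tdoa_triple(rx, ry, arrivals = c(1, 1, 1), c_ms = 1450)
#' @export
solve_tdoa_triple <- function(rx, ry, arrivals, c_ms = 1447) {
  stopifnot(length(rx) == 3, length(ry) == 3, length(arrivals) == 3,
            all(is.finite(c(rx, ry, arrivals))), c_ms > 0)
  area2 <- abs((rx[2] - rx[1]) * (ry[3] - ry[1]) - (rx[3] - rx[1]) * (ry[2] - ry[1]))
  if (area2 / 2 <= 1e-6) {
    stop("degenerate geometry: receivers are (nearly) collinear", call. = FALSE)
  }
  a <- arrivals
  c2 <- c_ms^2
  # pairwise-differenced range equations: A %*% p = b0 + b1 * t0
  A <- 2 * rbind(c(rx[2] - rx[1], ry[2] - ry[1]),
                 c(rx[3] - rx[1], ry[3] - ry[1]))
  sq <- rx^2 + ry^2
  b0 <- c(sq[2] - sq[1] - c2 * (a[2]^2 - a[1]^2),
          sq[3] - sq[1] - c2 * (a[3]^2 - a[1]^2))
  b1 <- 2 * c2 * c(a[2] - a[1], a[3] - a[1])
  Ainv <- solve(A)
  p0 <- Ainv %*% b0
  p1 <- Ainv %*% b1
  # substitute p(t0) into the first range equation -> quadratic in t0
  u <- c(p0[1] - rx[1], p0[2] - ry[1])
  v <- c(p1[1], p1[2])
  qa <- sum(v^2) - c2
  qb <- 2 * sum(u * v) + 2 * c2 * a[1]
  qc <- sum(u^2) - c2 * a[1]^2
  roots <- solve_quadratic(qa, qb, qc)
  roots <- roots[roots < min(a) + 1e-9]
  if (length(roots) == 0) return(empty_solutions())
  purrr::map_dfr(roots, function(t0) {
    p <- p0 + p1 * t0
    s <- tryCatch(tdoa_sensitivity(p[1], p[2], rx, ry, c_ms),
                  error = function(e) NA_real_)
    tibble::tibble(x_m = p[1], y_m = p[2], t0_s = t0, sensitivity = s)
  })
}

empty_solutions <- function() {
  tibble::tibble(x_m = numeric(), y_m = numeric(), t0_s = numeric(),
                 sensitivity = numeric())
}

# Real roots of qa*t^2 + qb*t + qc = 0, numerically stable; tolerates a
# discriminant pushed slightly negative by rounding.
solve_quadratic <- function(qa, qb, qc) {
  scale <- max(abs(qa), abs(qb), abs(qc))
  if (scale == 0) return(numeric())
  if (abs(qa) < 1e-14 * scale) {
    if (abs(qb) < 1e-14 * scale) return(numeric())
    return(-qc / qb)
  }
  disc <- qb^2 - 4 * qa * qc
  if (disc < 0) {
    if (disc > -1e-10 * max(qb^2, 1)) disc <- 0 else return(numeric())
  }
  q <- -(qb + sign(qb + (qb == 0)) * sqrt(disc)) / 2
  r1 <- q / qa
  r2 <- if (q != 0) qc / q else r1
  unique(c(r1, r2))
}

#' Error sensitivity of a TDOA solution
#'
#' Quantifies how strongly the solved position reacts to arrival-time
#' error: the Frobenius norm of the 2x3 Jacobian of the position with
#' respect to the three arrival times, in m/s — a geometric dilution of
#' precision. Computed in closed form by implicitly differentiating the
#' range equations: with unit vectors `u_i` from receiver `i` to the
#' tag, the Jacobian of `(x, y, t0)` is `c * M^-1` where row `i` of `M`
#' is `(u_i, c)`; the position rows of that matrix are measured.
#' Subsets whose geometry amplifies timing error score high and are
#' down-weighted by [combine_position()].
#'
#' @param x,y Tag position, m.
#' @param rx,ry Receiver coordinates, length-3 numeric, m.
#' @param c_ms Sound speed, m/s.
#' @param method `"analytic"` (closed form, default) or `"numeric"`
#'   (central finite differences on the solver, step 1e-7 s).
#' @param arrivals Arrival times, required for `method = "numeric"`.
#' @return Sensitivity in metres of position displacement per second of
#'   arrival-time perturbation; strictly positive.
#' @export
tdoa_sensitivity <- function(x, y, rx, ry, c_ms = 1447,
                             method = c("analytic", "numeric"),
                             arrivals = NULL) {
  method <- match.arg(method)
  if (method == "numeric") {
    if (is.null(arrivals)) stop("`arrivals` required for numeric sensitivity", call. = FALSE)
    return(tdoa_sensitivity_fd(x, y, rx, ry, arrivals, c_ms))
  }
  d <- plane_distance(x, y, rx, ry)
  if (any(d < 1e-9)) stop("tag coincides with a receiver; sensitivity undefined", call. = FALSE)
  M <- cbind((x - rx) / d, (y - ry) / d, c_ms)
  J <- tryCatch(c_ms * solve(M)[1:2, , drop = FALSE],
                error = function(e) stop("singular geometry for sensitivity", call. = FALSE))
  sqrt(sum(J^2))
}

# Finite-difference sensitivity: perturb each arrival, re-solve, take the
# candidate nearest the unperturbed position.
tdoa_sensitivity_fd <- function(x, y, rx, ry, arrivals, c_ms, h = 1e-7) {
  J <- matrix(NA_real_, 2, 3)
  for (j in 1:3) {
    shift <- function(sgn) {
      a <- arrivals
      a[j] <- a[j] + sgn * h
      sols <- solve_tdoa_triple(rx, ry, a, c_ms)
      if (nrow(sols) == 0) stop("no solution under perturbation", call. = FALSE)
      i <- which.min(plane_distance(sols$x_m, sols$y_m, x, y))
      c(sols$x_m[i], sols$y_m[i])
    }
    J[, j] <- (shift(1) - shift(-1)) / (2 * h)
  }
  sqrt(sum(J^2))
}

#' Combine subset solutions into one position fix
#'
#' The subset solutions for one transmission are averaged with weights
#' `1 / sensitivity^2`, so the position is dominated by the subsets
#' whose geometry is least sensitive to timing error. The emission time
#' is combined with the same weights. The fix's reported `sensitivity`
#' is the minimum over the subsets used.
#'
#' @param solutions Tibble of subset solutions (`x_m`, `y_m`, `t0_s`,
#'   `sensitivity`), one row per three-receiver subset.
#' @return One-row tibble: `time_s` (emission-time estimate), `x_m`,
#'   `y_m`, `sensitivity`, `n_subsets`.
#' @examples
#' sols <- tibble::tibble(x_m = c(0, 10), y_m = 0, t0_s = 0,
#'                        sensitivity = c(1, 3))
#' combine_position(sols) # x = 0.9: the noisier subset contributes 1/10
#' @export
combine_position <- function(solutions) {
  stopifnot(is.data.frame(solutions))
  if (nrow(solutions) == 0) stop("no subset solutions to combine", call. = FALSE)
  w <- 1 / solutions$sensitivity^2
  tibble::tibble(
    time_s = sum(w * solutions$t0_s) / sum(w),
    x_m = sum(w * solutions$x_m) / sum(w),
    y_m = sum(w * solutions$y_m) / sum(w),
    sensitivity = min(solutions$sensitivity),
    n_subsets = nrow(solutions)
  )
}

# Solve all 3-receiver subsets of one detection group and resolve the
# two-root ambiguity: (i) drop candidates farther than 3 array diameters
# from the array centroid; (ii) if some subsets are unambiguous, their
# mean position anchors the choice for the rest; (iii) otherwise keep
# each subset's lower-sensitivity root.
solve_group <- function(group, array, c_ms) {
  idx <- match(group$receiver_id, array$receiver_id)
  if (anyNA(idx)) stop("detection from a receiver not in the array", call. = FALSE)
  cen <- c(mean(array$x_m), mean(array$y_m))
  diam <- max(stats::dist(array[, c("x_m", "y_m")]))
  subsets <- utils::combn(seq_len(nrow(group)), 3, simplify = FALSE)
  cand <- purrr::map(subsets, function(s) {
    rx <- array$x_m[idx[s]]
    ry <- array$y_m[idx[s]]
    sols <- tryCatch(solve_tdoa_triple(rx, ry, group$time_s[s], c_ms),
                     error = function(e) empty_solutions())
    sols <- sols[is.finite(sols$sensitivity) &
                   plane_distance(sols$x_m, sols$y_m, cen[1], cen[2]) <= 3 * diam, ]
    sols
  })
  cand <- cand[vapply(cand, nrow, 0L) > 0]
  if (length(cand) == 0) return(NULL)
  single <- vapply(cand, nrow, 0L) == 1
  picked <- if (any(single)) {
    anchor <- dplyr::bind_rows(cand[single])
    ax <- mean(anchor$x_m); ay <- mean(anchor$y_m)
    purrr::map_dfr(cand, function(s) s[which.min(plane_distance(s$x_m, s$y_m, ax, ay)), ])
  } else {
    purrr::map_dfr(cand, function(s) s[which.min(s$sensitivity), ])
  }
  combine_position(picked)
}

#' Position all transmissions in a detection table
#'
#' The full positioning pipeline: detections are grouped into
#' transmissions ([group_transmissions()]), every three-receiver subset
#' of each group is solved ([solve_tdoa_triple()]), ambiguous roots are
#' resolved by cross-subset consistency, and each transmission's subsets
#' are merged by the sensitivity-weighted mean ([combine_position()]).
#' No quality filtering is applied to the resulting fixes.
#'
#' @inheritParams group_transmissions
#' @return A tibble of position fixes, time-ordered within tag:
#'   `tag_id`, `time_s`, `x_m`, `y_m`, `sensitivity`, `n_receivers`.
#' @examples
#' set.seed(2)
#' arr <- default_array()
#' tr <- stationary_trajectory(25, -10, 30)
#' det <- simulate_detections(arr, tr, gen_transmission_times(30, 1, 2),
#'                            propagation_model(sigma_t = 0))
#' position_run(det, arr)
#' @export
position_run <- function(detections, array, c_ms = 1447, guard_s = 0.05) {
  grouped <- group_transmissions(detections, array, c_ms, guard_s)
  if (nrow(grouped) == 0) {
    return(tibble::tibble(tag_id = character(), time_s = numeric(),
                          x_m = numeric(), y_m = numeric(),
                          sensitivity = numeric(), n_receivers = integer()))
  }
  grouped |>
    dplyr::group_by(.data$tag_id, .data$transmission) |>
    dplyr::group_modify(function(g, key) {
      fix <- solve_group(g, array, c_ms)
      if (is.null(fix)) return(tibble::tibble())
      fix$n_receivers <- nrow(g)
      fix
    }) |>
    dplyr::ungroup() |>
    dplyr::select("tag_id", "time_s", "x_m", "y_m", "sensitivity", "n_receivers") |>
    dplyr::arrange(.data$tag_id, .data$time_s)
}
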