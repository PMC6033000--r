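# Local planar coordinate handling. All positioning runs in a local
# east/north frame (metres) so that position error is a plain Euclidean
# distance; geographic input is projected about a local origin.

EARTH_RADIUS_M <- 6371000

check_latlon <- function(lat, lon, what = "coordinate") {
  if (any(!is.finite(lat)) || any(!is.finite(lon))) {
    stop(sprintf("non-finite %s", what), call. = FALSE)
  }
  if (any(lat < -90 | lat > 90)) {
    stop(sprintf("%s latitude out of range [-90, 90]", what), call. = FALSE)
  }
  if (any(lon < -180 | lon > 180)) {
    stop(sprintf("%s longitude out of range [-180, 180]", what), call. = FALSE)
  }
  invisible(NULL)
}

#' Project geographic coordinates to a local planar frame
#'
#' Converts WGS84 latitude/longitude to metres east (`x_m`) and north
#' (`y_m`) of a local origin, using an equirectangular projection:
#' `x = R * cos(lat0) * dlon`, `y = R * dlat` (angles in radians,
#' `R` = 6371 km). The projection is locally conformal and exactly
#' invertible ([local_to_latlon()]); at the sub-kilometre scales of a
#' receiver array the round-trip error is far below a millimetre.
#'
#' @param data A data frame with `lat` and `lon` columns (decimal degrees).
#' @param origin Origin of the local frame as `c(lat, lon)`. Default
#'   `NULL` uses the centroid (mean lat/lon) of `data`.
#' @return A tibble: `data` with `x_m` and `y_m` columns added (metres
#'   east/north of the origin) and the origin stored in the
#'   `"origin"` attribute.
#' @seealso [local_to_latlon()], [plane_distance()]
#' @examples
#' rec <- tibble::tibble(lat = c(56.130, 56.131), lon = c(-4.61, -4.61))
#' latlon_to_local(rec, origin = c(56.130, -4.61))
#' @export
latlon_to_local <- function(data, origin = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("lat", "lon") %in% names(data))) {
    stop("`data` must have `lat` and `lon` columns", call. = FALSE)
  }
  check_latlon(data$lat, data$lon)
  if (is.null(origin)) origin <- c(mean(data$lat), mean(data$lon))
  check_latlon(origin[1], origin[2], "origin")
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    x_m = EARTH_RADIUS_M * cos(origin[1] * pi / 180) *
      (.data$lon - origin[2]) * pi / 180,
    y_m = EARTH_RADIUS_M * (.data$lat - origin[1]) * pi / 180
  )
  attr(out, "origin") <- origin
  out
}

#' Invert the local planar projection back to latitude/longitude
#'
#' Exact inverse of [latlon_to_local()] for the same `origin`.
#'
#' @param data A data frame with `x_m` and `y_m` columns (metres).
#' @param origin Origin of the local frame as `c(lat, lon)`; if missing,
#'   taken from the `"origin"` attribute left by [latlon_to_local()].
#' @return A tibble with `lat` and `lon` columns added.
#' @export
local_to_latlon <- function(data, origin = NULL) {
  stopifnot(is.data.frame(data))
  if (!all(c("x_m", "y_m") %in% names(data))) {
    stop("`data` must have `x_m` and `y_m` columns", call. = FALSE)
  }
  if (is.null(origin)) origin <- attr(data, "origin")
  if (is.null(origin)) stop("`origin` not given and not stored on `data`", call. = FALSE)
  check_latlon(origin[1], origin[2], "origin")
  dplyr::mutate(
    tibble::as_tibble(data),
    lat = origin[1] + (.data$y_m / EARTH_RADIUS_M) * 180 / pi,
    lon = origin[2] + (.data$x_m / (EARTH_RADIUS_M * cos(origin[1] * pi / 180))) * 180 / pi
  )
}

#' Euclidean distance in the local planar frame
#'
#' Plain Pythagorean distance between points in metres; the measure used
#' for every accuracy and precision statistic in the package. Vectorised
#' over its arguments.
#'
#' @param x1,y1,x2,y2 Coordinates in metres.
#' @return Numeric vector of distances in metres.
#' @examples
#' plane_distance(0, 0, 3, 4) # 5
#' @export
plane_distance <- function(x1, y1, x2, y2) {
  if (any(!is.finite(c(x1, y1, x2, y2)))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  sqrt((x2 - x1)^2 + (y2 - y1)^2)
}
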