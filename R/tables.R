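# Delimited-table plumbing: comma-separated files with a header row, one
# record per line. Times are normalised to epoch seconds on read; columns
# are validated against a named schema so downstream code can rely on
# types.

tel_schemas <- list(
  receivers  = list(required = "receiver_id", position = TRUE,  time = FALSE),
  detections = list(required = c("receiver_id", "tag_id"), position = FALSE, time = TRUE),
  fixes      = list(required = "tag_id", position = TRUE, time = TRUE),
  gps        = list(required = character(), position = TRUE, time = TRUE)
)

# Accepts epoch seconds (numeric or numeric-looking strings) and ISO-8601
# datetimes ("2016-11-02T10:00:00Z" or with a space), mixed freely within
# one column; returns epoch seconds (UTC).
parse_time_column <- function(x, col) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  iso <- which(is.na(out) & !is.na(x))
  if (length(iso)) {
    parsed <- tryCatch(
      as.POSIXct(gsub("T", " ", sub("Z$", "", x[iso])),
                 tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")),
      error = function(e) as.POSIXct(NA)
    )
    out[iso] <- as.numeric(parsed)
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable time in column `%s`, row %d: \"%s\"",
                 col, bad[1], x[bad[1]]), call. = FALSE)
  }
  out
}

#' Read a telemetry table
#'
#' Reads a comma-separated file with a header row against one of the
#' package's table schemas and normalises times to epoch seconds.
#'
#' Schemas and their required columns:
#' \describe{
#'   \item{`"receivers"`}{`receiver_id` plus either `x_m`/`y_m` or `lat`/`lon`.}
#'   \item{`"detections"`}{`receiver_id`, `tag_id`, and a time column.}
#'   \item{`"fixes"`}{`tag_id`, a time column, and `x_m`/`y_m` or `lat`/`lon`.}
#'   \item{`"gps"`}{a time column and `x_m`/`y_m` or `lat`/`lon`.}
#' }
#' The time column may be named `time_s` (epoch seconds) or `time`
#' (epoch seconds or ISO-8601 datetimes); it is returned as numeric
#' `time_s`. Geographic coordinates are projected with
#' [latlon_to_local()] when `origin` is supplied.
#'
#' @param path Path to a comma-separated file with a header.
#' @param schema One of `"receivers"`, `"detections"`, `"fixes"`, `"gps"`.
#' @param origin Optional `c(lat, lon)` origin used to project `lat`/`lon`
#'   input to the local planar frame.
#' @return A tibble with validated columns; times as numeric `time_s`.
#' @export
read_tel_table <- function(path, schema, origin = NULL) {
  schema <- match.arg(schema, names(tel_schemas))
  sc <- tel_schemas[[schema]]
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(dat) == 0) {
    stop(sprintf("empty table: %s", path), call. = FALSE)
  }
  missing <- setdiff(sc$required, names(dat))
  if (length(missing)) {
    stop(sprintf("missing column(s) %s in %s (no header or wrong schema?)",
                 paste0("`", missing, "`", collapse = ", "), path), call. = FALSE)
  }
  if (sc$time) {
    tcol <- intersect(c("time_s", "time"), names(dat))[1]
    if (is.na(tcol)) stop(sprintf("missing time column (`time_s` or `time`) in %s", path), call. = FALSE)
    dat$time_s <- parse_time_column(dat[[tcol]], tcol)
    if (tcol != "time_s") dat[[tcol]] <- NULL
  }
  if (sc$position) {
    if (all(c("x_m", "y_m") %in% names(dat))) {
      # already planar
    } else if (all(c("lat", "lon") %in% names(dat))) {
      dat <- latlon_to_local(dat, origin = origin)
    } else {
      stop(sprintf("missing position columns (`x_m`/`y_m` or `lat`/`lon`) in %s", path),
           call. = FALSE)
    }
  }
  tibble::as_tibble(dat)
}

#' Write a telemetry table
#'
#' Writes records as comma-separated text with a header row; the inverse
#' of [read_tel_table()] (write then read returns identical records).
#'
#' @param data A data frame of records.
#' @param path Output file path.
#' @return `data`, invisibly.
#' @export
write_tel_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
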