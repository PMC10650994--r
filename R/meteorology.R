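# Hourly meteorological factors: data model, CSV I/O, physical-consistency
# utilities, and image-to-observation pairing.

METEO_FACTORS <- c("T_h", "RH_h", "AP_h", "TD_h", "VP_h")
METEO_COLUMNS <- c("timestamp", METEO_FACTORS)

# Magnus constants (over water): saturation vapor pressure
# e_s(T) = 6.112 * exp(beta * T / (lambda + T)) hPa.
MAGNUS_BETA <- 17.62
MAGNUS_LAMBDA <- 243.12

#' Construct a validated table of hourly meteorological records
#'
#' A `meteo_table` holds one row per observation hour with the five hourly
#' factors used throughout the pipeline: air temperature `T_h` (degrees C),
#' relative humidity `RH_h` (%), atmospheric pressure `AP_h` (hPa), dew-point
#' temperature `TD_h` (degrees C) and vapor pressure `VP_h` (hPa).
#'
#' Validation enforces: `RH_h` in \[0, 100\] and `VP_h > 0` (errors);
#' `AP_h` in \[800, 1100\] (plausibility warning only); `TD_h <= T_h`
#' (warning for observed data, where sensor noise can produce small
#' violations; error when `source = "synthetic"`, where the generator is
#' required to be physically consistent). Timestamps must be unique; rows
#' are sorted by time.
#'
#' @param data data.frame with columns `timestamp` (POSIXct or ISO-8601
#'   character) and `T_h`, `RH_h`, `AP_h`, `TD_h`, `VP_h` (numeric).
#' @param source label recording where the records came from, e.g.
#'   `"station"`, `"greenhouse"` or `"synthetic"`.
#' @return A `meteo_table` (a data.frame sorted by timestamp).
#' @export
meteo_table <- function(data, source = "station") {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(METEO_COLUMNS, names(data))
  if (length(missing_cols) > 0L) {
    stop("meteo table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, METEO_COLUMNS]
  data$timestamp <- parse_iso8601(data$timestamp)
  if (anyNA(data$timestamp)) {
    bad <- which(is.na(data$timestamp))
    stop("unparseable timestamp in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (col in METEO_FACTORS) {
    if (!is.numeric(data[[col]])) {
      stop("column ", col, " must be numeric", call. = FALSE)
    }
  }
  bad_rh <- which(data$RH_h < 0 | data$RH_h > 100)
  if (length(bad_rh) > 0L) {
    stop("RH_h outside [0, 100] in row(s): ", paste(bad_rh, collapse = ", "),
         call. = FALSE)
  }
  bad_vp <- which(data$VP_h <= 0)
  if (length(bad_vp) > 0L) {
    stop("VP_h must be positive; violated in row(s): ",
         paste(bad_vp, collapse = ", "), call. = FALSE)
  }
  bad_td <- which(data$TD_h > data$T_h + 1e-9)
  if (length(bad_td) > 0L) {
    msg <- paste0("TD_h exceeds T_h in row(s): ", paste(bad_td, collapse = ", "))
    if (identical(source, "synthetic")) stop(msg, call. = FALSE)
    warning(msg, " (kept; treated as sensor noise)", call. = FALSE)
  }
  bad_ap <- which(data$AP_h < 800 | data$AP_h > 1100)
  if (length(bad_ap) > 0L) {
    warning("AP_h outside plausibility bounds [800, 1100] hPa in row(s): ",
            paste(bad_ap, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(data$timestamp)) {
    stop("duplicate timestamps in meteo table", call. = FALSE)
  }
  data <- data[order(data$timestamp), , drop = FALSE]
  rownames(data) <- NULL
  structure(data, source = source, class = c("meteo_table", "data.frame"))
}

# Parse ISO-8601 timestamps ("2021-06-13T07:00:00" or with a space); naive
# local times are stored as UTC so arithmetic is timezone-free.
parse_iso8601 <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  x <- as.character(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"),
                    optional = TRUE)
  out
}

format_iso8601 <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

#' Read hourly meteorological records from CSV
#'
#' Expects a UTF-8 comma-separated file with header columns exactly
#' `timestamp, T_h, RH_h, AP_h, TD_h, VP_h` and ISO-8601 timestamps.
#'
#' @param path file path.
#' @param source source label stored on the returned table.
#' @return A validated [meteo_table()].
#' @seealso [write_meteo_csv()]
#' @export
read_meteo_csv <- function(path, source = "station") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(METEO_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("CSV ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- parse_iso8601(raw$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts)) + 1L  # +1 for the header line
    stop("unparseable timestamp in ", path, " at line(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw$timestamp <- ts
  meteo_table(raw, source = source)
}

#' Write a meteo table to CSV
#'
#' Inverse of [read_meteo_csv()]: `read_meteo_csv(write_meteo_csv(x, f))`
#' reproduces `x` on validated tables.
#'
#' @param x a [meteo_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_meteo_csv <- function(x, path) {
  stopifnot(inherits(x, "meteo_table"))
  out <- as.data.frame(x)
  out$timestamp <- format_iso8601(out$timestamp)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Dew-point temperature from air temperature and relative humidity
#'
#' Magnus inversion with beta = 17.62, lambda = 243.12 degrees C:
#' `f = log(RH/100) + beta*T/(lambda+T)`, `TD = lambda*f/(beta - f)`.
#' At saturation (`RH = 100`) the dew point equals the air temperature, and
#' `TD <= T` always. Used by the synthetic generator to keep `TD_h`
#' consistent with `T_h` and `RH_h`; observed CSV columns are taken as-is
#' and never recomputed.
#'
#' @param t air temperature, degrees C (vectorized).
#' @param rh relative humidity, % in (0, 100\].
#' @return dew-point temperature, degrees C.
#' @export
dew_point_from_t_rh <- function(t, rh) {
  if (any(rh <= 0)) stop("relative humidity must be positive", call. = FALSE)
  if (any(rh > 100)) stop("relative humidity cannot exceed 100%", call. = FALSE)
  f <- log(rh / 100) + MAGNUS_BETA * t / (MAGNUS_LAMBDA + t)
  MAGNUS_LAMBDA * f / (MAGNUS_BETA - f)
}

#' Vapor pressure from dew-point temperature
#'
#' Magnus saturation vapor pressure evaluated at the dew point:
#' `VP = 6.112 * exp(beta*TD/(lambda+TD))` hPa. Strictly increasing in `TD`.
#'
#' @param td dew-point temperature, degrees C in \[-60, 60\] (vectorized).
#' @return vapor pressure, hPa.
#' @export
vapor_pressure_from_td <- function(td) {
  if (any(td < -60 | td > 60)) {
    stop("dew-point temperature outside supported range [-60, 60] degrees C",
         call. = FALSE)
  }
  6.112 * exp(MAGNUS_BETA * td / (MAGNUS_LAMBDA + td))
}

#' Pair image timestamps with the nearest hourly observation
#'
#' Photographs are taken just after the hour (e.g. 07:04) while station
#' records are on the hour; each image is paired with the nearest-in-time
#' record no further than `max_gap_min` minutes away. Ties between two
#' equidistant records go to the earlier record. Images with no record in
#' range are reported, never silently dropped.
#'
#' @param image_times POSIXct (or ISO-8601 character) vector of image
#'   timestamps.
#' @param meteo a [meteo_table()].
#' @param max_gap_min maximum pairing gap, minutes (default 30).
#' @return list with `pairs` (data.frame: `image`, `record` row indices,
#'   `gap_min`) and `unmatched` (data.frame: `image`, `nearest_gap_min`).
#' @export
match_images_to_hours <- function(image_times, meteo, max_gap_min = 30) {
  stopifnot(inherits(meteo, "meteo_table"))
  if (nrow(meteo) == 0L) stop("meteo table is empty", call. = FALSE)
  if (max_gap_min < 0) stop("max_gap_min must be non-negative", call. = FALSE)
  image_times <- parse_iso8601(image_times)
  rec <- as.numeric(meteo$timestamp)
  img <- as.numeric(image_times)
  idx <- integer(length(img))
  gap <- numeric(length(img))
  for (i in seq_along(img)) {
    d <- abs(rec - img[i])
    # ties (equidistant records) break to the earlier record: which.min
    # returns the first minimum and rec is sorted ascending
    j <- which.min(d)
    idx[i] <- j
    gap[i] <- d[j] / 60
  }
  ok <- gap <= max_gap_min
  list(
    pairs = data.frame(image = which(ok), record = idx[ok],
                       gap_min = gap[ok]),
    unmatched = data.frame(image = which(!ok), nearest_gap_min = gap[!ok])
  )
}
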