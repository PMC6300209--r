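# Reading, smoothing, cleaning and daily partitioning of location streams.
#
# Locations are held in a plain data.frame with columns
# cow_id (character), timestamp (POSIXct), x, y (metres), sorted by cow
# then time. Exclusion accounting is carried in attributes so that
# input count = retained + sum of exclusions at every stage.

#' Read a delimited location file
#'
#' Expects a header with (configurable) columns for animal id, timestamp,
#' x and y. Rows with unparseable coordinates or timestamps are dropped and
#' counted; duplicate timestamps within a cow collapse to the last record.
#'
#' @param path Path to a delimited text file.
#' @param sep Field delimiter (default comma).
#' @param col_map Named character vector mapping the canonical names
#'   `cow_id`, `timestamp`, `x`, `y` to the file's column names.
#' @param tz Timezone used to parse timestamps (default UTC).
#' @return data.frame of locations with attribute `n_dropped` (unparseable
#'   rows) and `n_duplicates` (collapsed duplicate timestamps).
#' @export
read_locations <- function(path, sep = ",",
                           col_map = c(cow_id = "cow_id", timestamp = "timestamp",
                                       x = "x", y = "y"),
                           tz = "UTC") {
  if (!file.exists(path)) stop("location file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    warning("empty location file: ", path)
    out <- empty_locations()
    attr(out, "n_dropped") <- 0L
    attr(out, "n_duplicates") <- 0L
    return(out)
  }
  need <- c("cow_id", "timestamp", "x", "y")
  miss <- need[!col_map[need] %in% names(raw)]
  if (length(miss))
    stop("location file is missing required column(s): ",
         paste(col_map[miss], collapse = ", "))
  df <- data.frame(
    cow_id = raw[[col_map["cow_id"]]],
    timestamp = parse_time(raw[[col_map["timestamp"]]], tz),
    x = suppressWarnings(as.numeric(raw[[col_map["x"]]])),
    y = suppressWarnings(as.numeric(raw[[col_map["y"]]])),
    stringsAsFactors = FALSE
  )
  bad <- is.na(df$timestamp) | !is.finite(df$x) | !is.finite(df$y) |
    is.na(df$cow_id) | df$cow_id == ""
  n_dropped <- sum(bad)
  df <- df[!bad, , drop = FALSE]
  df <- df[order(df$cow_id, df$timestamp), , drop = FALSE]
  # duplicate timestamps within a cow keep the last record
  dup <- duplicated(df[, c("cow_id", "timestamp")], fromLast = TRUE)
  n_dup <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "n_dropped") <- n_dropped
  attr(df, "n_duplicates") <- n_dup
  df
}

parse_time <- function(s, tz) {
  t <- as.POSIXct(s, tz = tz, format = "%Y-%m-%dT%H:%M:%S")
  alt <- is.na(t)
  if (any(alt)) t[alt] <- as.POSIXct(s[alt], tz = tz)
  t
}

empty_locations <- function() {
  data.frame(cow_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
             x = numeric(), y = numeric(), stringsAsFactors = FALSE)
}

#' Write locations to a delimited text file
#'
#' Inverse of [read_locations()]: writes `cow_id,timestamp,x,y` with
#' ISO-8601 timestamps.
#'
#' @param locations Location data.frame.
#' @param path Output path.
#' @param sep Field delimiter.
#' @export
write_locations <- function(locations, path, sep = ",") {
  out <- data.frame(
    cow_id = locations$cow_id,
    timestamp = format(locations$timestamp, "%Y-%m-%dT%H:%M:%S", tz = time_tz(locations)),
    x = format(locations$x, digits = 15, trim = TRUE, scientific = FALSE),
    y = format(locations$y, digits = 15, trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

time_tz <- function(locations) {
  tz <- attr(locations$timestamp, "tzone")
  if (is.null(tz) || tz == "") "UTC" else tz
}

#' Simple moving average smoothing
#'
#' Replaces each coordinate by the mean of up to `window` samples centred
#' on it, computed independently per cow. At the stream edges the window
#' truncates to the available samples. Timestamps are unchanged. The
#' default 15-sample window corresponds to two minutes at 0.125 Hz.
#'
#' @param locations Location data.frame.
#' @param window Odd window length in samples.
#' @return Smoothed location data.frame.
#' @export
smooth_sma <- function(locations, window = 15) {
  if (window %% 2 == 0) stop("SMA window must be odd (centring undefined)")
  stopifnot(window >= 1)
  if (window == 1 || nrow(locations) == 0) return(locations)
  half <- (window - 1) / 2
  for (id in unique(locations$cow_id)) {
    i <- which(locations$cow_id == id)
    locations$x[i] <- sma_vec(locations$x[i], half)
    locations$y[i] <- sma_vec(locations$y[i], half)
  }
  locations
}

# centred truncated moving average via cumulative sums
sma_vec <- function(v, half) {
  n <- length(v)
  if (n == 1 || half == 0) return(v)
  cs <- cumsum(v)
  idx <- seq_len(n)
  hi <- pmin(idx + half, n)
  lo <- pmax(idx - half, 1L)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Is a timestamp inside a milking window?
#'
#' @param timestamp POSIXct vector.
#' @param milking A [milking_schedule()].
#' @param tz Local timezone defining the clock (defaults to the timestamps').
#' @return Logical vector.
#' @export
in_milking_window <- function(timestamp, milking, tz = NULL) {
  stopifnot(inherits(milking, "milking_schedule"))
  if (is.null(tz)) tz <- if (is.null(attr(timestamp, "tzone"))) "UTC" else attr(timestamp, "tzone")
  lt <- as.POSIXlt(timestamp, tz = tz)
  mins <- lt$hour * 60 + lt$min + lt$sec / 60
  out <- rep(FALSE, length(timestamp))
  for (s in milking$start_min) {
    e <- s + milking$duration_min
    out <- out | (mins >= s & mins < e)
    if (e > 1440) out <- out | (mins < e - 1440)  # window wrapping midnight
  }
  out
}

#' Clean a location stream
#'
#' Removes samples falling inside a milking window (reason `milking`) and
#' samples outside the upper-barn rectangle (reason `out_of_barn`), in that
#' order. Idempotent; counts for both reasons are attached as the
#' `exclusions` attribute so that input = retained + sum(exclusions).
#'
#' @param locations Location data.frame (usually smoothed).
#' @param geometry A [barn_geometry()].
#' @param tz Local timezone for the milking clock.
#' @return Cleaned data.frame with attribute `exclusions`
#'   (named counts `milking`, `out_of_barn`).
#' @export
clean_locations <- function(locations, geometry, tz = NULL) {
  stopifnot(inherits(geometry, "barn_geometry"))
  milk <- in_milking_window(locations$timestamp, geometry$milking, tz)
  oob <- !milk & !point_in_rect(locations$x, locations$y, geometry$barn,
                                closed_max = TRUE)
  keep <- !milk & !oob
  out <- locations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- c(milking = sum(milk), out_of_barn = sum(oob))
  out
}

#' Partition a location stream by calendar day
#'
#' @param locations Cleaned location data.frame.
#' @param tz Local timezone defining day boundaries (local midnight).
#' @return The data.frame with additional columns `date` (Date) and
#'   `day` (1-based index of the date within the cow's observed span, so
#'   gap days keep their slot).
#' @export
split_by_day <- function(locations, tz = NULL) {
  if (is.null(tz)) tz <- time_tz(locations)
  locations$date <- as.Date(locations$timestamp, tz = tz)
  locations$day <- as.integer(locations$date - min(locations$date)) + 1L
  locations
}

#' Per cow-day list of location data.frames
#'
#' @param locations Output of [split_by_day()].
#' @return Nested list: `out[[cow_id]][[day]]` is that day's data.frame
#'   (possibly with zero rows for gap days).
#' @export
cow_day_split <- function(locations) {
  stopifnot("day" %in% names(locations))
  days <- seq_len(max(locations$day))
  out <- list()
  for (id in unique(locations$cow_id)) {
    sub <- locations[locations$cow_id == id, , drop = FALSE]
    out[[id]] <- lapply(days, function(d) {
      r <- sub[sub$day == d, , drop = FALSE]
      rownames(r) <- NULL
      r
    })
  }
  out
}
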