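# Basic space-use measures S1-S10 and the per-cow feature table.

#' Distance moved per hour for one cow-day
#'
#' Sums Euclidean step lengths between consecutive retained samples,
#' excluding steps that bridge a recording gap longer than `max_gap`
#' seconds (milking absences, battery failures), and divides by the
#' observed duration in hours (sum of non-bridged inter-sample intervals).
#'
#' @param day_locations Cleaned, smoothed location data.frame for one
#'   cow-day with >= 2 rows.
#' @param max_gap Gap threshold in seconds; steps spanning a longer
#'   interval are excluded from both distance and duration. The default is
#'   5 nominal 8 s intervals.
#' @return Metres per hour, or `NA` for fewer than 2 samples.
#' @export
distance_per_hour <- function(day_locations, max_gap = 40) {
  n <- nrow(day_locations)
  if (n < 2) return(NA_real_)
  dt <- as.numeric(diff(day_locations$timestamp), units = "secs")
  keep <- dt <= max_gap
  if (!any(keep)) return(NA_real_)
  d <- sqrt(diff(day_locations$x)^2 + diff(day_locations$y)^2)
  sum(d[keep]) / (sum(dt[keep]) / 3600)
}

#' Mean position of a location stream
#'
#' @param locations Location data.frame with >= 1 row.
#' @return Named vector `c(x, y)`, `NA` if empty.
#' @export
mean_position <- function(locations) {
  if (nrow(locations) == 0) return(c(x = NA_real_, y = NA_real_))
  c(x = mean(locations$x), y = mean(locations$y))
}

#' Zone occupancy proportions from a utilisation distribution
#'
#' Sums cell masses whose centres lie in each zone of interest. The
#' passage mass is `1 - (F + C_T)` by construction of the zone tiling.
#'
#' @param ud A normalised `barn_ud`.
#' @param geometry A [barn_geometry()].
#' @return Named vector of proportions `F`, `C_T`, `C1`, `C2`, `C3`, `P`;
#'   all `NA` for an empty distribution.
#' @export
zone_proportions <- function(ud, geometry) {
  stopifnot(inherits(ud, "barn_ud"), inherits(geometry, "barn_geometry"))
  nm <- c("F", "C_T", "C1", "C2", "C3", "P")
  if (ud$empty) return(stats::setNames(rep(NA_real_, 6), nm))
  cc <- cell_centres(ud$grid)
  v <- ud_vector(ud)
  zmass <- function(rects) {
    if (inherits(rects, "barn_rect")) rects <- list(rects)
    keep <- rep(FALSE, length(v))
    for (r in rects) keep <- keep | point_in_rect(cc$x, cc$y, r)
    sum(v[keep])
  }
  f <- zmass(geometry$zones$F)
  c1 <- zmass(geometry$zones$C1); c2 <- zmass(geometry$zones$C2)
  c3 <- zmass(geometry$zones$C3)
  ct <- c1 + c2 + c3
  stats::setNames(c(f, ct, c1, c2, c3, 1 - (f + ct)), nm)
}

#' Daily full- and core-range sizes
#'
#' @param uds List of daily `barn_ud` objects.
#' @param levels `c(full, core)` isopleth levels.
#' @return List with per-day sizes (`full`, `core`; NA for empty days) and
#'   their across-day means `S9`, `S10`.
#' @export
range_sizes <- function(uds, levels = c(0.95, 0.50)) {
  full <- vapply(uds, function(u)
    if (isTRUE(u$empty)) NA_real_ else as.numeric(isopleth(u, levels[1])$size), 0)
  core <- vapply(uds, function(u)
    if (isTRUE(u$empty)) NA_real_ else as.numeric(isopleth(u, levels[2])$size), 0)
  list(full = full, core = core,
       S9 = mean(full, na.rm = TRUE), S10 = mean(core, na.rm = TRUE))
}

#' Space-use summary S1-S10 for one cow
#'
#' Computes daily values of each basic measure and averages across the
#' available (non-empty) days.
#'
#' @param day_list List of cleaned, smoothed per-day location data.frames
#'   for one cow (as from [cow_day_split()]).
#' @param geometry A [barn_geometry()].
#' @param grid A [grid_spec()].
#' @param levels Isopleth levels `c(full, core)`.
#' @param max_gap Gap threshold for [distance_per_hour()].
#' @return List with `summary` (named vector S1-S10), `uds` (daily
#'   distributions, reused by the fidelity battery), `days_used`, and
#'   `unusable` flag (no usable day at all).
#' @export
summarize_cow <- function(day_list, geometry, grid = grid_spec(),
                          levels = c(0.95, 0.50), max_gap = 40) {
  uds <- lapply(day_list, build_ud, grid = grid)
  usable <- !vapply(uds, function(u) u$empty, TRUE)
  daily <- matrix(NA_real_, nrow = length(day_list), ncol = 8,
                  dimnames = list(NULL, paste0("S", 1:8)))
  for (d in which(usable)) {
    df <- day_list[[d]]
    mp <- mean_position(df)
    zp <- zone_proportions(uds[[d]], geometry)
    daily[d, ] <- c(distance_per_hour(df, max_gap), mp["x"], mp["y"],
                    zp["F"], zp["C_T"], zp["C1"], zp["C2"], zp["C3"])
  }
  rs <- range_sizes(uds, levels)
  s <- c(colMeans(daily, na.rm = TRUE), S9 = rs$S9, S10 = rs$S10)
  s[is.nan(s)] <- NA_real_
  list(summary = s, uds = uds, days_used = sum(usable),
       unusable = !any(usable))
}

#' Full per-cow feature table S1-S16
#'
#' Runs the standard pipeline per cow: SMA smoothing, milking/out-of-barn
#' cleaning, daily partition, daily utilisation distributions, basic
#' measures S1-S10 and the site-fidelity battery S11-S16.
#'
#' @param locations Raw location data.frame for the herd.
#' @param geometry A [barn_geometry()].
#' @param grid A [grid_spec()].
#' @param window SMA window in samples.
#' @param levels Isopleth levels `c(full, core)`.
#' @param max_gap Gap threshold in seconds for S1.
#' @param scheme Fidelity aggregation scheme.
#' @param tz Local timezone for milking clock and day boundaries.
#' @return data.frame, one row per cow: `cow_id`, `S1`..`S16`, `days_used`,
#'   with attribute `exclusions` from cleaning.
#' @export
build_feature_table <- function(locations, geometry, grid = grid_spec(),
                                window = 15, levels = c(0.95, 0.50),
                                max_gap = 40, scheme = "consecutive",
                                tz = NULL) {
  sm <- smooth_sma(locations, window)
  cl <- clean_locations(sm, geometry, tz)
  cl <- split_by_day(cl, tz)
  per_cow <- cow_day_split(cl)
  rows <- lapply(names(per_cow), function(id) {
    sc <- summarize_cow(per_cow[[id]], geometry, grid, levels, max_gap)
    fid <- fidelity_battery(sc$uds, geometry, levels, scheme)
    data.frame(cow_id = id, t(c(sc$summary, fid)),
               days_used = sc$days_used, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "exclusions") <- attr(cl, "exclusions")
  out
}

#' Write / read the feature table
#'
#' @param features Feature table from [build_feature_table()].
#' @param path Delimited text path.
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE,
                    colClasses = c(cow_id = "character"))
}
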