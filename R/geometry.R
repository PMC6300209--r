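# Barn geometry: rectangles, zones, milking schedule, grid specification.

#' Axis-aligned rectangle
#'
#' @param xmin,xmax,ymin,ymax Rectangle bounds in metres.
#' @return A named numeric vector of class `barn_rect`.
#' @export
barn_rect <- function(xmin, xmax, ymin, ymax) {
  stopifnot(is.numeric(xmin), is.numeric(xmax), is.numeric(ymin), is.numeric(ymax),
            xmax > xmin, ymax > ymin)
  structure(c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "barn_rect")
}

#' Default zone rectangles for the upper barn area
#'
#' F is the feeding strip, P the passage to the milking parlour, and C1-C3
#' the three cubicle blocks; C_T (their union) is derived, not stored.
#'
#' @return Named list of [barn_rect()] objects `F`, `P`, `C1`, `C2`, `C3`.
#' @export
default_zones <- function() {
  list(
    F  = barn_rect(0, 53, 10, 20),
    P  = barn_rect(53, 60, 10, 20),
    C1 = barn_rect(40, 60, 20, 30),
    C2 = barn_rect(20, 40, 20, 30),
    C3 = barn_rect(0, 20, 20, 30)
  )
}

#' Milking schedule
#'
#' @param starts Character vector of clock times ("HH:MM") at which milking
#'   starts each day.
#' @param duration_min Duration of each milking absence in minutes. The farm
#'   routine is approximately 90 minutes, so this is configurable.
#' @return List of class `milking_schedule` with `start_min` (minutes after
#'   local midnight) and `duration_min`.
#' @export
milking_schedule <- function(starts = c("05:00", "13:00", "21:00"),
                             duration_min = 90) {
  stopifnot(duration_min > 0)
  parts <- strsplit(starts, ":", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  if (!all(ok)) stop("milking start times must be 'HH:MM'")
  start_min <- vapply(parts, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
  if (anyNA(start_min) || any(start_min < 0 | start_min >= 1440))
    stop("milking start times must be valid clock times")
  structure(list(start_min = sort(start_min), duration_min = duration_min),
            class = "milking_schedule")
}

#' Barn geometry
#'
#' Describes the upper barn rectangle, its named zones and the milking
#' schedule. Zone membership is half-open (`[min, max)` on each axis) with
#' the global barn maximum edges closed, so every in-barn point maps to
#' exactly one zone.
#'
#' @param barn [barn_rect()] for the upper barn area.
#' @param zones Named list of [barn_rect()]s; must contain `F`, `P`, `C1`,
#'   `C2`, `C3`.
#' @param milking A [milking_schedule()].
#' @return Object of class `barn_geometry`.
#' @export
barn_geometry <- function(barn = barn_rect(0, 60, 10, 30),
                          zones = default_zones(),
                          milking = milking_schedule()) {
  required <- c("F", "P", "C1", "C2", "C3")
  missing_z <- setdiff(required, names(zones))
  if (length(missing_z))
    stop("geometry is missing zone(s): ", paste(missing_z, collapse = ", "))
  for (z in zones) {
    if (z["xmin"] < barn["xmin"] || z["xmax"] > barn["xmax"] ||
        z["ymin"] < barn["ymin"] || z["ymax"] > barn["ymax"])
      stop("all zones must lie inside the barn rectangle")
  }
  structure(list(barn = barn, zones = zones, milking = milking),
            class = "barn_geometry")
}

#' @export
print.barn_geometry <- function(x, ...) {
  b <- x$barn
  cat(sprintf("Barn geometry: x in [%g, %g], y in [%g, %g] m\n",
              b["xmin"], b["xmax"], b["ymin"], b["ymax"]))
  cat("Zones:", paste(names(x$zones), collapse = ", "), "\n")
  cat(sprintf("Milking: %d events/day of %g min (starting %s after midnight)\n",
              length(x$milking$start_min), x$milking$duration_min,
              paste(sprintf("%02d:%02d", x$milking$start_min %/% 60,
                            x$milking$start_min %% 60), collapse = ", ")))
  invisible(x)
}

# Half-open point-in-rectangle test; closed_max closes the max edges
# (used for the global barn boundary so x = 60 stays in barn).
point_in_rect <- function(x, y, rect, closed_max = FALSE) {
  if (closed_max)
    x >= rect["xmin"] & x <= rect["xmax"] & y >= rect["ymin"] & y <= rect["ymax"]
  else
    x >= rect["xmin"] & x < rect["xmax"] & y >= rect["ymin"] & y < rect["ymax"]
}

#' Assign points to zones
#'
#' @param x,y Coordinates in metres.
#' @param geometry A [barn_geometry()].
#' @return Character vector of zone names; `NA` for points outside the barn.
#' @export
zone_of <- function(x, y, geometry) {
  stopifnot(inherits(geometry, "barn_geometry"))
  out <- rep(NA_character_, length(x))
  barn <- geometry$barn
  inb <- point_in_rect(x, y, barn, closed_max = TRUE)
  # clamp the closed max edges onto the half-open zone grid
  eps <- 1e-9
  xx <- ifelse(x >= barn["xmax"], barn["xmax"] - eps, x)
  yy <- ifelse(y >= barn["ymax"], barn["ymax"] - eps, y)
  for (nm in names(geometry$zones)) {
    hit <- inb & is.na(out) & point_in_rect(xx, yy, geometry$zones[[nm]])
    out[hit] <- nm
  }
  out
}

#' Grid specification for the utilisation distribution
#'
#' The default is a 40 x 13 grid of 1.5 m cells over the upper barn area.
#' Thirteen rows of 1.5 m cover only 19.5 of the 20 m depth; the residual
#' 0.5 m strip at the top is merged into the last row so that no in-barn
#' point is left unbinned.
#'
#' @param x0,y0 Grid origin (lower-left corner) in metres.
#' @param cell Cell side length in metres.
#' @param nx,ny Number of columns and rows.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(x0 = 0, y0 = 10, cell = 1.5, nx = 40, ny = 13) {
  stopifnot(cell > 0, nx >= 1, ny >= 1)
  structure(list(x0 = x0, y0 = y0, cell = cell,
                 nx = as.integer(nx), ny = as.integer(ny)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("Grid: %d x %d cells of %g m (origin %g, %g), %d cells total\n",
              x$nx, x$ny, x$cell, x$x0, x$y0, x$nx * x$ny))
  invisible(x)
}

n_cells <- function(grid) grid$nx * grid$ny

# Cell centres in row-major order (row 1 = bottom row, columns fastest).
cell_centres <- function(grid) {
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$cell
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$cell
  list(x = rep(cx, times = grid$ny), y = rep(cy, each = grid$nx))
}

#' Number of samples in a moving-average window of a given duration
#'
#' @param minutes Window duration in minutes.
#' @param rate Sampling rate in Hz.
#' @return Odd integer sample count covering the window (a 2-minute window
#'   at 0.125 Hz gives 15 samples).
#' @export
sma_window_samples <- function(minutes, rate) {
  stopifnot(minutes > 0, rate > 0)
  n <- floor(minutes * 60 * rate)
  as.integer(if (n %% 2 == 0) n + 1 else n)
}

#' Nominal sample slots for a study
#'
#' @param n_days Number of study days.
#' @param rate Sampling rate in Hz.
#' @return Number of nominal sample slots per animal (5 days at 0.125 Hz
#'   gives 54,000).
#' @export
nominal_samples <- function(n_days, rate) {
  stopifnot(n_days >= 1, rate > 0)
  n_days * 24 * 3600 * rate
}
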