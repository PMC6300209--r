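# Utilisation distributions on the virtual grid, isopleth ranges,
# truncation and zone restriction.

#' Build a daily utilisation distribution by cell counting
#'
#' Each in-barn location is assigned to the grid cell containing it
#' (`floor((x - x0)/cell)`, with the top/right boundary clamped into the
#' last cell) and counts are normalised to a discrete probability
#' distribution. A point falling outside the grid extent indicates a
#' cleaning failure and raises an error.
#'
#' @param day_locations Cleaned location data.frame for one cow-day.
#' @param grid A [grid_spec()].
#' @return Object of class `barn_ud`: list with `mass` (ny x nx matrix,
#'   row 1 = bottom row), `grid`, `total_count`, and `empty` flag.
#' @export
build_ud <- function(day_locations, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"))
  n <- nrow(day_locations)
  mass <- matrix(0, nrow = grid$ny, ncol = grid$nx)
  if (n == 0) {
    return(structure(list(mass = mass, grid = grid, total_count = 0L,
                          empty = TRUE), class = "barn_ud"))
  }
  col <- floor((day_locations$x - grid$x0) / grid$cell)
  row <- floor((day_locations$y - grid$y0) / grid$cell)
  # clamp closed top/right boundary (and the merged residual strip) into
  # the last cell
  col[col == grid$nx] <- grid$nx - 1
  row[row >= grid$ny] <- grid$ny - 1
  if (any(col < 0 | col >= grid$nx | row < 0 | row >= grid$ny))
    stop("point outside grid extent; locations must be cleaned before binning")
  idx <- row * grid$nx + col + 1  # row-major linear index
  counts <- tabulate(idx, nbins = n_cells(grid))
  mass <- matrix(counts / n, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  structure(list(mass = mass, grid = grid, total_count = n, empty = FALSE),
            class = "barn_ud")
}

#' @export
print.barn_ud <- function(x, ...) {
  cat(sprintf("Utilisation distribution: %d x %d grid, %d points, %d occupied cells%s\n",
              x$grid$nx, x$grid$ny, x$total_count, sum(x$mass > 0),
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

# row-major mass vector (row 1 first, columns fastest)
ud_vector <- function(ud) as.vector(t(ud$mass))

ud_from_vector <- function(v, grid, total_count = NA_integer_) {
  structure(list(mass = matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE),
                 grid = grid, total_count = total_count,
                 empty = sum(v) <= 0), class = "barn_ud")
}

#' Isopleth cell set of a utilisation distribution
#'
#' Cells are sorted by decreasing mass (ties broken by row-major cell
#' index) and included greedily until the cumulative mass first reaches
#' the level; the crossing cell is included.
#'
#' @param ud A [build_ud()] result.
#' @param level Fraction in (0, 1]; 0.50 gives the core range and 0.95
#'   the full range.
#' @param include_ties If `TRUE`, all cells whose mass equals the last
#'   included cell's mass are included as well (alternative tie mode).
#' @return Object of class `isopleth`: list with `level`, `cells`
#'   (row-major linear indices), `size` (cell count) and `empty` flag.
#' @export
isopleth <- function(ud, level, include_ties = FALSE) {
  stopifnot(inherits(ud, "barn_ud"), level > 0, level <= 1)
  v <- ud_vector(ud)
  if (sum(v) <= 0) {
    return(structure(list(level = level, cells = integer(), size = 0L,
                          empty = TRUE), class = "isopleth"))
  }
  occ <- which(v > 0)
  ord <- occ[order(-v[occ], occ)]
  cum <- cumsum(v[ord])
  k <- which(cum >= level - 1e-12)[1]
  if (is.na(k)) k <- length(ord)  # guard against rounding below the level
  if (include_ties && k < length(ord)) {
    last_mass <- v[ord[k]]
    while (k < length(ord) && v[ord[k + 1]] == last_mass) k <- k + 1
  }
  cells <- sort(ord[seq_len(k)])
  structure(list(level = level, cells = cells, size = length(cells),
                 empty = FALSE), class = "isopleth")
}

#' @export
print.isopleth <- function(x, ...) {
  cat(sprintf("%g%% isopleth: %d cells%s\n", 100 * x$level, x$size,
              if (x$empty) " [empty]" else ""))
  invisible(x)
}

#' Truncate a utilisation distribution at an isopleth level
#'
#' Zeroes mass outside the isopleth cell set and renormalises the
#' remainder to 1.
#'
#' @inheritParams isopleth
#' @return A `barn_ud`.
#' @export
truncate_ud <- function(ud, level, include_ties = FALSE) {
  iso <- isopleth(ud, level, include_ties)
  if (iso$empty) return(ud)
  v <- ud_vector(ud)
  keep <- rep(FALSE, length(v))
  keep[iso$cells] <- TRUE
  v[!keep] <- 0
  v <- v / sum(v)
  ud_from_vector(v, ud$grid, ud$total_count)
}

#' Restrict a utilisation distribution to a zone
#'
#' Keeps cells whose centre lies inside the zone rectangle (half-open on
#' each axis, max edges closed at the barn boundary by construction of the
#' grid) and renormalises. A zero-mass restriction is flagged `empty`.
#'
#' @param ud A `barn_ud`.
#' @param rect A [barn_rect()] (or union of rectangles given as a list).
#' @return A `barn_ud`.
#' @export
restrict_ud <- function(ud, rect) {
  stopifnot(inherits(ud, "barn_ud"))
  rects <- if (inherits(rect, "barn_rect")) list(rect) else rect
  cc <- cell_centres(ud$grid)
  keep <- rep(FALSE, n_cells(ud$grid))
  for (r in rects) keep <- keep | point_in_rect(cc$x, cc$y, r)
  v <- ud_vector(ud)
  v[!keep] <- 0
  s <- sum(v)
  if (s <= 0) {
    out <- ud_from_vector(v, ud$grid, ud$total_count)
    out$empty <- TRUE
    return(out)
  }
  ud_from_vector(v / s, ud$grid, ud$total_count)
}

#' Cubicle-area rectangle union for a geometry
#'
#' @param geometry A [barn_geometry()].
#' @return List of the three cubicle-block rectangles (C_T = C1 u C2 u C3).
#' @export
cubicle_union <- function(geometry) {
  geometry$zones[c("C1", "C2", "C3")]
}

#' Export a utilisation distribution as delimited text plus JSON sidecar
#'
#' Writes the dense mass matrix (`ny` rows by `nx` columns, top row first)
#' and a sidecar `<path>.json` with the grid specification and total count.
#'
#' @param ud A `barn_ud`.
#' @param path Output path for the matrix.
#' @export
write_ud <- function(ud, path) {
  m <- ud$mass[rev(seq_len(ud$grid$ny)), , drop = FALSE]
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  side <- list(grid = ud$grid[c("x0", "y0", "cell", "nx", "ny")],
               total_count = ud$total_count, empty = ud$empty)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
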