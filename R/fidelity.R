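# Site fidelity: Bhattacharyya overlap between daily utilisation
# distributions, aggregation schemes, and the six-score battery.

#' Bhattacharyya coefficient between two utilisation distributions
#'
#' Computes `sum(sqrt(U1(q) * U2(q)))` over grid cells, the affinity form
#' of the coefficient, which is 1 for identical distributions and 0 for
#' disjoint supports. (The plain-product form `sum(U1 * U2)`, which does
#' not attain 1 at full overlap except for point masses, is available via
#' `form = "product"` for comparison.)
#'
#' @param ud1,ud2 `barn_ud` objects on the same grid, both normalised.
#' @param form `"affinity"` (default) or `"product"`.
#' @return Similarity in `[0, 1]`; `NA` if either distribution is empty.
#' @export
bhattacharyya <- function(ud1, ud2, form = c("affinity", "product")) {
  form <- match.arg(form)
  stopifnot(inherits(ud1, "barn_ud"), inherits(ud2, "barn_ud"))
  if (!identical(ud1$grid[c("x0", "y0", "cell", "nx", "ny")],
                 ud2$grid[c("x0", "y0", "cell", "nx", "ny")]))
    stop("utilisation distributions are on different grids")
  if (ud1$empty || ud2$empty) return(NA_real_)
  v1 <- ud_vector(ud1); v2 <- ud_vector(ud2)
  s <- if (form == "affinity") sum(sqrt(v1 * v2)) else sum(v1 * v2)
  min(max(s, 0), 1)  # clip floating-point overshoot
}

#' Pairwise Bhattacharyya matrix over daily distributions
#'
#' @param uds List of `barn_ud` objects (one per day; empty days allowed).
#' @param form Passed to [bhattacharyya()].
#' @return Symmetric matrix with `NA` rows/columns for empty days and 1 on
#'   the diagonal for usable days.
#' @export
fidelity_matrix <- function(uds, form = "affinity") {
  n <- length(uds)
  m <- matrix(NA_real_, n, n)
  usable <- !vapply(uds, function(u) isTRUE(u$empty), TRUE)
  for (i in seq_len(n)) {
    if (!usable[i]) next
    m[i, i] <- 1
    for (j in seq_len(n)[-seq_len(i)]) {
      if (!usable[j]) next
      m[i, j] <- m[j, i] <- bhattacharyya(uds[[i]], uds[[j]], form)
    }
  }
  m
}

#' Aggregate daily overlap into a single site-fidelity score
#'
#' `consecutive` (the canonical scheme) averages the n-1 adjacent-day
#' coefficients; `all_pairs` averages all C(n,2) unordered pairs;
#' `weighted_pairs` is an all-pairs mean weighted by `1/|i - j|`
#' (normalised). Pairs involving an empty day are dropped.
#'
#' @param uds List of daily `barn_ud` objects (>= 2 usable).
#' @param scheme One of `"consecutive"`, `"all_pairs"`, `"weighted_pairs"`.
#' @param form Passed to [bhattacharyya()].
#' @return List with `score`, `n_pairs` used and `scheme`; `score` is `NA`
#'   when fewer than one usable pair exists.
#' @export
aggregate_fidelity <- function(uds,
                               scheme = c("consecutive", "all_pairs", "weighted_pairs"),
                               form = "affinity") {
  scheme <- match.arg(scheme)
  m <- fidelity_matrix(uds, form)
  n <- length(uds)
  if (scheme == "consecutive") {
    pairs <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  } else {
    pairs <- t(utils::combn(n, 2))
  }
  vals <- m[pairs]
  w <- if (scheme == "weighted_pairs") 1 / abs(pairs[, 1] - pairs[, 2]) else
    rep(1, nrow(pairs))
  ok <- !is.na(vals)
  if (!any(ok)) return(list(score = NA_real_, n_pairs = 0L, scheme = scheme))
  list(score = sum(w[ok] * vals[ok]) / sum(w[ok]),
       n_pairs = sum(ok), scheme = scheme)
}

#' The six site-fidelity measures S11-S16
#'
#' For each combination of region (full upper barn, feeding area F,
#' cubicle area C_T) and isopleth level (0.95 full range, 0.50 core
#' range), each daily distribution is restricted to the region, truncated
#' at the isopleth level of the restricted distribution, renormalised, and
#' the consecutive-day Bhattacharyya mean is taken. The restrict-then-
#' truncate order is fixed.
#'
#' @param uds List of daily `barn_ud` objects for one cow.
#' @param geometry A [barn_geometry()].
#' @param levels Isopleth levels, full range first (default `c(0.95, 0.50)`).
#' @param scheme Aggregation scheme (default consecutive days).
#' @param form Passed to [bhattacharyya()].
#' @return Named numeric vector `S11`..`S16` (NA where a region is never
#'   visited), with attribute `n_pairs` per score.
#' @export
fidelity_battery <- function(uds, geometry, levels = c(0.95, 0.50),
                             scheme = "consecutive", form = "affinity") {
  stopifnot(inherits(geometry, "barn_geometry"), length(levels) == 2)
  regions <- list(barn = geometry$barn, F = geometry$zones$F,
                  C_T = cubicle_union(geometry))
  out <- numeric(0); np <- integer(0)
  for (lv in levels) {
    for (rg in regions) {
      sub <- lapply(uds, function(u) {
        if (isTRUE(u$empty)) return(u)
        r <- restrict_ud(u, rg)
        if (r$empty) r else truncate_ud(r, lv)
      })
      agg <- aggregate_fidelity(sub, scheme, form)
      out <- c(out, agg$score)
      np <- c(np, agg$n_pairs)
    }
  }
  names(out) <- paste0("S", 11:16)
  attr(out, "n_pairs") <- stats::setNames(np, names(out))
  out
}
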