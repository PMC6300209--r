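# Fixture builders shared across the suite. Everything is generated in
# code; no binary fixtures.

# a location data.frame from vectors (timestamps in seconds from a fixed
# origin unless POSIXct given)
make_locs <- function(x, y, t = seq_along(x) * 8, cow_id = "c1",
                      origin = as.POSIXct("2014-01-13 00:00:00", tz = "UTC")) {
  stamp <- if (inherits(t, "POSIXct")) t else origin + t
  data.frame(cow_id = rep(cow_id, length.out = length(x)), timestamp = stamp,
             x = x, y = y, stringsAsFactors = FALSE)
}

# a barn_ud with prescribed row-major masses on an arbitrary small grid
make_ud <- function(mass, nx, ny, cell = 1, x0 = 0, y0 = 0,
                    total_count = 100L) {
  stopifnot(length(mass) == nx * ny)
  g <- grid_spec(x0 = x0, y0 = y0, cell = cell, nx = nx, ny = ny)
  structure(list(mass = matrix(mass, nrow = ny, ncol = nx, byrow = TRUE),
                 grid = g, total_count = total_count,
                 empty = sum(mass) <= 0), class = "barn_ud")
}

# a barn_ud on the standard barn grid with mass placed at given (x, y)
# metre positions in equal shares
barn_ud_at <- function(xs, ys, grid = grid_spec()) {
  build_ud(make_locs(xs, ys), grid)
}

# exhaustive oracle for the discrete isopleth: the minimum-cardinality
# prefix of the mass-sorted (ties by index) cell order whose sum reaches
# the level
isopleth_oracle <- function(mass, level) {
  occ <- which(mass > 0)
  ord <- occ[order(-mass[occ], occ)]
  tot <- 0; k <- 0
  for (i in ord) {
    k <- k + 1; tot <- tot + mass[i]
    if (tot >= level - 1e-12) break
  }
  sort(ord[seq_len(k)])
}

# independent Gaussian AICc evaluation for an lm fit:
# -2*loglik + 2k + 2k(k+1)/(n-k-1), k = slopes + intercept + sigma
aicc_oracle <- function(y, X) {
  n <- length(y)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  e <- y - X %*% beta
  s2 <- sum(e^2) / n  # ML variance estimate
  ll <- -n / 2 * (log(2 * pi * s2) + 1)
  k <- ncol(X) + 1
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# small metadata table for screen/classifier tests
make_meta <- function(n = 20, seed = 42) {
  set.seed(seed)
  data.frame(cow_id = sprintf("c%02d", seq_len(n)),
             lame = rep(c(1L, 0L), length.out = n),
             parity = sample(1:6, n, replace = TRUE),
             dim = sample(44:220, n, replace = TRUE),
             yield = round(rnorm(n, 42.5, 6.9), 1),
             stringsAsFactors = FALSE)
}

# a small, quick simulated herd shared by several tests (2 days keeps the
# runtime low while still exercising fidelity pairs)
small_herd <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_herd(sim_params(n_cows = 4, n_days = 2, seed = 99))
    cache
  }
})
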