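test_that("distance per hour: stationary, straight path, and gap handling", {
  still <- make_locs(x = rep(3, 10), y = rep(15, 10))
  expect_equal(distance_per_hour(still), 0)
  # 1 m per 8 s step for exactly one hour -> 450 m/h
  n <- 451
  path <- make_locs(x = seq_len(n) * 1.0, y = rep(15, n), t = seq_len(n) * 8)
  expect_equal(distance_per_hour(path), 450)
  # a 3 h gap between two clusters leaves the rate unchanged when
  # gap-bridging steps are excluded
  c1 <- make_locs(x = seq_len(50) * 1.0, y = rep(15, 50), t = seq_len(50) * 8)
  c2 <- make_locs(x = seq_len(50) * 1.0, y = rep(15, 50),
                  t = 3 * 3600 + 400 + seq_len(50) * 8)
  expect_equal(distance_per_hour(rbind(c1, c2)), distance_per_hour(c1))
  # fewer than 2 samples is flagged missing
  expect_true(is.na(distance_per_hour(make_locs(1, 15, t = 8))))
})

test_that("mean position", {
  expect_equal(mean_position(make_locs(30, 25, t = 8)), c(x = 30, y = 25))
  expect_equal(mean_position(make_locs(c(0, 60), c(10, 30), t = c(8, 16))),
               c(x = 30, y = 20))
  expect_true(all(is.na(mean_position(make_locs(numeric(0), numeric(0),
                                                t = numeric(0))))))
})

test_that("zone proportions: point masses and additivity", {
  geo <- barn_geometry()
  ud <- barn_ud_at(rep(10.7, 4), rep(15.7, 4))      # all mass in F
  zp <- zone_proportions(ud, geo)
  expect_equal(zp[["F"]], 1)
  expect_equal(zp[["C_T"]], 0)
  # quarter of the mass in each of C1, C2, C3, F
  ud <- barn_ud_at(c(45.7, 30.7, 10.7, 10.7), c(25.7, 25.7, 25.7, 15.7))
  zp <- zone_proportions(ud, geo)
  expect_equal(zp[["C_T"]], 0.75)
  expect_equal(unname(zp[c("C1", "C2", "C3")]), rep(0.25, 3))
  expect_equal(zp[["C_T"]], sum(zp[c("C1", "C2", "C3")]))
  # zone-mass conservation on arbitrary UDs
  set.seed(13)
  ud <- barn_ud_at(runif(500, 0, 60), runif(500, 10, 30))
  zp <- zone_proportions(ud, geo)
  expect_equal(zp[["F"]] + zp[["P"]] + zp[["C_T"]], 1, tolerance = 1e-9)
  # empty UD is flagged missing
  expect_true(all(is.na(zone_proportions(build_ud(
    make_locs(numeric(0), numeric(0), t = numeric(0)), grid_spec()), geo))))
})

test_that("occupancy shares are recovered by the generator", {
  # FEED share 0.3, zero sensor noise: S4 should recover 0.3
  p <- sim_params(n_cows = 6, n_days = 2, seed = 17, noise_sd = 0,
                  state_prob = c(FEED = 0.3, C1 = 0.2, C2 = 0.2, C3 = 0.2,
                                 PASSAGE = 0.1))
  h <- generate_herd(p)
  ft <- build_feature_table(h$locations, barn_geometry())
  se <- sd(ft$S4) / sqrt(nrow(ft))
  expect_lt(abs(mean(ft$S4) - 0.3), 5 * se)
})

test_that("range sizes average daily isopleth counts", {
  u <- barn_ud_at(10.7, 15.7)   # single-cell UD
  rs <- range_sizes(rep(list(u), 3))
  expect_equal(rs$S9, 1); expect_equal(rs$S10, 1)
  # hand-built two days with known sizes
  u2 <- barn_ud_at(c(10.7, 20.2, 30.7, 40.2), c(15.7, 15.7, 25.7, 25.7))
  rs <- range_sizes(list(u, u2))
  expect_equal(rs$full, c(1, 4))
  expect_equal(rs$S9, 2.5)
  expect_lte(rs$S10, rs$S9)
})

test_that("summarize_cow averages daily values and flags missing days", {
  geo <- barn_geometry()
  # two identical days -> summary equals a single day's values
  d1 <- make_locs(x = c(10.2, 10.9, 11.3), y = c(15.1, 15.4, 15.2))
  d2 <- d1; d2$timestamp <- d2$timestamp + 86400
  same <- summarize_cow(list(d1, d2), geo)
  one <- summarize_cow(list(d1), geo)
  expect_equal(same$summary, one$summary)
  expect_equal(same$days_used, 2)
  # hand-built 2-day fixture: S2 means
  d3 <- make_locs(x = c(20, 22), y = c(15, 15))
  d3$timestamp <- d3$timestamp + 2 * 86400
  mixed <- summarize_cow(list(d1, d3), geo)
  expect_equal(mixed$summary[["S2"]],
               mean(c(mean(d1$x), mean(d3$x))))
  # an empty day is skipped, not averaged as zero
  with_gap <- summarize_cow(list(d1, d1[0, ], d2), geo)
  expect_equal(with_gap$days_used, 2)
  expect_equal(with_gap$summary, same$summary)
  # all days empty -> unusable
  expect_true(summarize_cow(list(d1[0, ]), geo)$unusable)
})

test_that("feature table over a simulated herd has full shape and no flags", {
  h <- small_herd()
  ft <- build_feature_table(h$locations, barn_geometry())
  expect_equal(nrow(ft), 4)
  expect_named(ft, c("cow_id", paste0("S", 1:16), "days_used"))
  expect_false(anyNA(ft[, paste0("S", 1:16)]))
  expect_true(all(ft$days_used == 2))
  # invariants: proportions, additivity, nesting
  expect_true(all(ft$S4 >= 0 & ft$S4 <= 1))
  expect_equal(ft$S5, ft$S6 + ft$S7 + ft$S8, tolerance = 1e-9)
  expect_true(all(ft$S10 <= ft$S9))
  expect_true(all(ft[, paste0("S", 11:16)] >= 0 & ft[, paste0("S", 11:16)] <= 1))
})

test_that("S1 is invariant to day ordering and milking removal", {
  h <- small_herd()
  geo <- barn_geometry()
  sm <- smooth_sma(h$locations, 15)
  cl <- split_by_day(clean_locations(sm, geo))
  cd <- cow_day_split(cl)[[1]]
  s1_fwd <- mean(vapply(cd, distance_per_hour, 0))
  s1_rev <- mean(vapply(rev(cd), distance_per_hour, 0))
  expect_equal(s1_fwd, s1_rev)
})
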