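test_that("Bhattacharyya coefficient: limits and the two-cell hand value", {
  u1 <- make_ud(c(0.5, 0.5, 0, 0), nx = 4, ny = 1)
  expect_equal(bhattacharyya(u1, u1), 1)
  disj <- make_ud(c(0, 0, 0.5, 0.5), nx = 4, ny = 1)
  expect_equal(bhattacharyya(u1, disj), 0)
  u2 <- make_ud(c(0.25, 0.75, 0, 0), nx = 4, ny = 1)
  expect_equal(bhattacharyya(u1, u2), sqrt(0.125) + sqrt(0.375),
               tolerance = 1e-12)
  expect_equal(round(bhattacharyya(u1, u2), 5), 0.96593)
  # the plain-product form does not reach 1 at full overlap
  expect_equal(bhattacharyya(u1, u1, form = "product"), 0.5)
  # mismatched grids are a domain error; empty distributions give NA
  expect_error(bhattacharyya(u1, make_ud(c(1, 0), nx = 2, ny = 1)), "grid")
  expect_true(is.na(bhattacharyya(u1, make_ud(rep(0, 4), 4, 1))))
})

test_that("pairwise matrix is symmetric, reflexive and bounded", {
  set.seed(31)
  uds <- lapply(1:4, function(i)
    barn_ud_at(runif(200, 0, 60), runif(200, 10, 30)))
  m <- fidelity_matrix(uds)
  expect_equal(m, t(m))
  expect_equal(diag(m), rep(1, 4))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("aggregation schemes: counts, means and degenerate cases", {
  # identical UDs across 5 days -> 1 under every scheme
  u <- barn_ud_at(c(10.7, 30.2), c(15.7, 25.1))
  same <- rep(list(u), 5)
  for (sch in c("consecutive", "all_pairs", "weighted_pairs"))
    expect_equal(aggregate_fidelity(same, sch)$score, 1)
  # 5 days -> 4 consecutive pairs, 10 unordered pairs
  expect_equal(aggregate_fidelity(same, "consecutive")$n_pairs, 4L)
  expect_equal(aggregate_fidelity(same, "all_pairs")$n_pairs, 10L)
  # a constructed sequence with known consecutive values
  # days: A, A, B, A, B where O(A,B) = o and O(A,A) = 1
  a <- make_ud(c(0.5, 0.5, 0, 0), nx = 4, ny = 1)
  b <- make_ud(c(0.25, 0.75, 0, 0), nx = 4, ny = 1)
  o <- bhattacharyya(a, b)
  seqd <- list(a, a, b, a, b)
  expect_equal(aggregate_fidelity(seqd, "consecutive")$score,
               mean(c(1, o, o, o)))
  # all-pairs equals consecutive when all pairwise values are equal
  two <- list(a, b)
  expect_equal(aggregate_fidelity(two, "all_pairs")$score,
               aggregate_fidelity(two, "consecutive")$score)
  # missing days drop their pairs
  holey <- list(a, make_ud(rep(0, 4), 4, 1), a)
  agg <- aggregate_fidelity(holey, "consecutive")
  expect_equal(agg$n_pairs, 0L)
  expect_true(is.na(agg$score))
  expect_equal(aggregate_fidelity(holey, "all_pairs")$n_pairs, 1L)
})

test_that("weighted_pairs uses 1/|i-j| weights", {
  a <- make_ud(c(1, 0), nx = 2, ny = 1)
  b <- make_ud(c(0.5, 0.5), nx = 2, ny = 1)
  o <- bhattacharyya(a, b)  # sqrt(0.5)
  # days: a, a, b -> pairs (1,2): 1 w=1; (1,3): o w=1/2; (2,3): o w=1
  expect_equal(aggregate_fidelity(list(a, a, b), "weighted_pairs")$score,
               (1 * 1 + 0.5 * o + 1 * o) / 2.5)
})

test_that("fidelity battery: identical days give 1, absent regions give NA", {
  geo <- barn_geometry()
  u <- barn_ud_at(c(10.7, 30.2, 45.5), c(15.7, 25.1, 28.3))
  fb <- fidelity_battery(rep(list(u), 5), geo)
  expect_equal(as.vector(fb), rep(1, 6))
  expect_named(fb, paste0("S", 11:16))
  # a cow that never enters F: S12/S15 missing, others defined
  cub <- barn_ud_at(c(10.3, 30.2), c(25.7, 25.1))
  fb <- fidelity_battery(rep(list(cub), 3), geo)
  expect_true(all(is.na(fb[c("S12", "S15")])))
  expect_false(anyNA(fb[c("S11", "S13", "S14", "S16")]))
})

test_that("restrict-then-truncate order is pinned", {
  geo <- barn_geometry()
  # mass: two F cells (0.25, 0.05) and two cubicle cells (0.5, 0.2).
  # restrict-to-F first makes both F cells survive the 0.9 truncation
  # (shares 5/6, 1/6); truncate-first at 0.9 would discard the 0.05 cell.
  mk <- function(w) {
    xs <- c(10.7, 20.2, 30.7, 40.2); ys <- c(15.7, 15.7, 25.7, 25.7)
    build_ud(make_locs(rep(xs, w), rep(ys, w)), grid_spec())
  }
  u1 <- mk(c(25, 5, 50, 20))
  u2 <- mk(c(5, 25, 20, 50))  # day 2 swaps the weights
  got <- fidelity_battery(list(u1, u2), geo, levels = c(0.90, 0.50))
  # independent hand value for the F-region 0.90-level score:
  # both days restrict to (5/6, 1/6) vs (1/6, 5/6)
  expect_equal(got[["S12"]], 2 * sqrt(5 / 6 * 1 / 6))
  # truncating before restricting would give a different answer
  tr_first <- bhattacharyya(restrict_ud(truncate_ud(u1, 0.90), geo$zones$F),
                            restrict_ud(truncate_ud(u2, 0.90), geo$zones$F))
  expect_false(isTRUE(all.equal(got[["S12"]], tr_first)))
})

test_that("cubicle-preference redraw for one group only lowers its fidelity", {
  # non-lame cows re-draw their cubicle anchors day-to-day; lame cows do
  # not: group-mean cubicle-area fidelity (S13) must be higher for lame
  p <- sim_params(n_cows = 8, n_days = 3, seed = 5,
                  anchor_jitter_sd = 6, lame_jitter_mult = 0,
                  jitter_cow_cv = 0, noise_sd = 0.5)
  h <- generate_herd(p)
  ft <- build_feature_table(h$locations, barn_geometry())
  lame <- h$metadata$lame == 1
  expect_gt(mean(ft$S13[lame]), mean(ft$S13[!lame]))
})
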