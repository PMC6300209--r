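# Synthetic herd generator: a continuous-time semi-Markov zone-occupancy
# process with within-zone reflected random walks, configurable lameness /
# parity / days-in-milk effects, and isotropic Gaussian sensor noise.

SIM_STATES <- c("FEED", "C1", "C2", "C3", "PASSAGE")

#' Simulation parameters for a synthetic herd
#'
#' Defaults describe the study design the package targets: 20 cows (half
#' lame) tracked for 5 days at 0.125 Hz with three daily 90-minute milking
#' absences, and effect directions matching the field observations (lame
#' cows feed less, rest more, and cover a smaller range; higher-parity
#' cows sit further towards the parlour passage; days in milk widens the
#' wander radius for non-lame cows and narrows it for lame cows).
#'
#' @param n_cows Number of cows (the lame/non-lame split is half/half,
#'   lame first surplus to the non-lame group when odd).
#' @param n_days Number of study days (>= 2; site fidelity needs pairs).
#' @param rate Sampling rate in Hz.
#' @param start Start of day 1 (POSIXct or string, local midnight).
#' @param milking A [milking_schedule()].
#' @param dwell_mean Named mean dwell times in minutes per behavioural
#'   state (`FEED`, `C1`, `C2`, `C3`, `PASSAGE`), all > 0.
#' @param state_prob Named baseline state probabilities (simplex).
#' @param lame_feed_shift Additive shift to the FEED probability for lame
#'   cows (negative).
#' @param lame_cubicle_shift Additive shift to total cubicle probability
#'   for lame cows (positive; split equally over C1-C3).
#' @param lame_radius_mult Multiplier (< 1) on the within-zone wander
#'   radius for lame cows.
#' @param parity_effect Metres of mean-x anchor shift per parity unit.
#' @param dim_slope Relative change in wander radius per day in milk
#'   (about its reference), for non-lame cows.
#' @param dim_ref Reference days-in-milk at which the DIM effect is zero.
#' @param dim_lame_sign Sign flip of the DIM slope for lame cows
#'   (-1 reproduces the negative lameness-by-DIM interaction).
#' @param base_radius Baseline within-zone wander half-width in metres.
#' @param step_sd Random-walk step standard deviation in metres per sample.
#' @param anchor_jitter_sd Day-to-day standard deviation (m) of the
#'   *cubicle* anchors, i.e. how much a cow's preferred resting spot is
#'   re-drawn between days. Feeding/passage anchors use the same scale
#'   for every cow.
#' @param lame_jitter_mult Multiplier on the cubicle-anchor
#'   `anchor_jitter_sd` for lame cows; values < 1 make lame cows re-draw
#'   their preferred cubicle spot less, giving them higher cubicle site
#'   fidelity. Neutral (1) by default: the canonical lameness effects are
#'   the occupancy shifts and the radius multiplier.
#' @param lame_feed_jitter_mult Multiplier on the feeding-anchor redraw
#'   for lame cows; values > 1 make lame cows less consistent about where
#'   along the feed face they feed (lower feeding-area site fidelity).
#'   Neutral (1) by default.
#' @param jitter_cow_cv Log-scale standard deviation of a per-cow
#'   lognormal multiplier on the anchor redraw, adding individual
#'   variability in site fidelity between cows.
#' @param noise_sd Isotropic Gaussian sensor noise standard deviation in
#'   metres (1 m matches an RTLS with 95% of fixes within 2 m).
#' @param parity_range Integer parity range to sample uniformly.
#' @param dim_range Days-in-milk range to sample uniformly.
#' @param yield_mean,yield_sd Mean daily milk yield distribution
#'   (litres/day; carried in metadata but unused by the analysis).
#' @param seed Integer seed; all per-cow streams derive from it.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(n_cows = 20, n_days = 5, rate = 0.125,
                       start = "2014-01-13",
                       milking = milking_schedule(),
                       dwell_mean = c(FEED = 18, C1 = 36, C2 = 36, C3 = 36,
                                      PASSAGE = 5),
                       state_prob = c(FEED = 0.32, C1 = 0.20, C2 = 0.22,
                                      C3 = 0.21, PASSAGE = 0.05),
                       lame_feed_shift = -0.062,
                       lame_cubicle_shift = 0.056,
                       lame_radius_mult = 0.8,
                       parity_effect = 3,
                       dim_slope = 0.0015,
                       dim_ref = 125,
                       dim_lame_sign = -1,
                       base_radius = 6.5,
                       step_sd = 0.6,
                       anchor_jitter_sd = 2.5,
                       lame_jitter_mult = 1,
                       lame_feed_jitter_mult = 1,
                       jitter_cow_cv = 0.35,
                       noise_sd = 1,
                       parity_range = c(1, 6),
                       dim_range = c(44, 220),
                       yield_mean = 42.5, yield_sd = 6.88,
                       seed = 1) {
  if (rate <= 0) stop("sample rate must be > 0")
  if (n_days < 2) stop("n_days must be >= 2 (site fidelity needs day pairs)")
  stopifnot(n_cows >= 1)
  dwell_mean <- dwell_mean[SIM_STATES]
  state_prob <- state_prob[SIM_STATES]
  if (anyNA(dwell_mean) || any(dwell_mean <= 0))
    stop("dwell_mean must name all states with positive minutes")
  if (anyNA(state_prob) || any(state_prob < 0))
    stop("state_prob must name all states with non-negative mass")
  if (abs(sum(state_prob) - 1) > 1e-8)
    stop("state_prob must sum to 1")
  structure(list(
    n_cows = as.integer(n_cows), n_days = as.integer(n_days), rate = rate,
    start = as.POSIXct(start, tz = "UTC"), milking = milking,
    dwell_mean = dwell_mean, state_prob = state_prob,
    lame_feed_shift = lame_feed_shift, lame_cubicle_shift = lame_cubicle_shift,
    lame_radius_mult = lame_radius_mult, parity_effect = parity_effect,
    dim_slope = dim_slope, dim_ref = dim_ref, dim_lame_sign = dim_lame_sign,
    base_radius = base_radius, step_sd = step_sd,
    anchor_jitter_sd = anchor_jitter_sd, lame_jitter_mult = lame_jitter_mult,
    lame_feed_jitter_mult = lame_feed_jitter_mult, jitter_cow_cv = jitter_cow_cv,
    noise_sd = noise_sd, parity_range = parity_range, dim_range = dim_range,
    yield_mean = yield_mean, yield_sd = yield_sd, seed = as.integer(seed)
  ), class = "sim_params")
}

#' Per-cow behavioural profile implied by metadata
#'
#' Applies the configured lameness, parity and days-in-milk effects to the
#' baseline state probabilities and wander radius. Probabilities are
#' clamped to `[0, 1]` and renormalised; the radius is floored at 0.5 m.
#'
#' @param metadata One-row data.frame (or list) with `lame`, `parity`,
#'   `dim`.
#' @param params A [sim_params()].
#' @return List with `probs` (simplex over states), `radius` (metres),
#'   `anchor_shift_x` (metres) and `jitter_sd` (metres).
#' @export
effect_profile <- function(metadata, params) {
  stopifnot(inherits(params, "sim_params"))
  L <- as.numeric(metadata$lame); P <- as.numeric(metadata$parity)
  D <- as.numeric(metadata$dim)
  p <- params$state_prob
  p["FEED"] <- p["FEED"] + params$lame_feed_shift * L
  p[c("C1", "C2", "C3")] <- p[c("C1", "C2", "C3")] +
    params$lame_cubicle_shift * L / 3
  p <- pmin(pmax(p, 0), 1)
  p <- p / sum(p)
  dim_factor <- 1 + params$dim_slope * (D - params$dim_ref) *
    ifelse(L == 1, params$dim_lame_sign, 1)
  radius <- max(params$base_radius * params$lame_radius_mult^L * dim_factor, 0.5)
  list(probs = p,
       radius = radius,
       anchor_shift_x = params$parity_effect * P,
       jitter_sd = c(FEED = params$anchor_jitter_sd * params$lame_feed_jitter_mult^L,
                     C1 = params$anchor_jitter_sd * params$lame_jitter_mult^L,
                     C2 = params$anchor_jitter_sd * params$lame_jitter_mult^L,
                     C3 = params$anchor_jitter_sd * params$lame_jitter_mult^L,
                     PASSAGE = params$anchor_jitter_sd))
}

# reflect values into [lo, hi] (triangle-wave fold)
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  if (any(w <= 0)) stop("degenerate reflection interval")
  z <- (v - lo) %% (2 * w)
  lo + ifelse(z > w, 2 * w - z, z)
}

# draw the semi-Markov state for each emitted slot time (seconds from start)
draw_state_sequence <- function(slot_sec, total_sec, probs, dwell_sec) {
  # over-draw segments until the timeline is covered
  segs_state <- integer(0); segs_len <- numeric(0)
  covered <- 0
  while (covered < total_sec) {
    k <- max(64, ceiling((total_sec - covered) / min(dwell_sec)) + 16)
    st <- sample.int(length(probs), k, replace = TRUE, prob = probs)
    len <- stats::rexp(k, rate = 1 / dwell_sec[st])
    segs_state <- c(segs_state, st); segs_len <- c(segs_len, len)
    covered <- covered + sum(len)
  }
  starts <- c(0, cumsum(segs_len))
  seg_of <- findInterval(slot_sec, starts, rightmost.closed = FALSE)
  list(state = segs_state[seg_of], segment = seg_of)
}

# zone rectangle lookup in simulator state order
state_zone <- function(geometry) {
  list(FEED = geometry$zones$F, C1 = geometry$zones$C1,
       C2 = geometry$zones$C2, C3 = geometry$zones$C3,
       PASSAGE = geometry$zones$P)
}

#' Generate a synthetic herd
#'
#' Simulates one trajectory per cow: a semi-Markov chain over the five
#' zone states with exponential dwell times; within each dwell a reflected
#' random walk around a per-zone daily anchor point, confined to the zone
#' rectangle; isotropic Gaussian sensor noise added afterwards. Samples in
#' milking windows are deleted (the cows are out of the barn). Output is
#' byte-identical for a fixed seed.
#'
#' @param params A [sim_params()].
#' @param geometry A [barn_geometry()]; must define zones F, P, C1-C3.
#' @return List with `locations` (data.frame `cow_id,timestamp,x,y`) and
#'   `metadata` (data.frame `cow_id,lame,parity,dim,yield`).
#' @export
generate_herd <- function(params, geometry = barn_geometry()) {
  stopifnot(inherits(params, "sim_params"), inherits(geometry, "barn_geometry"))
  zones <- state_zone(geometry)
  if (any(vapply(zones, is.null, TRUE)))
    stop("geometry is missing a zone required by the simulator")
  n <- params$n_cows
  ids <- sprintf("%04d", 1000 + seq_len(n))

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(params$seed)
  n_lame <- n %/% 2
  metadata <- data.frame(
    cow_id = ids,
    lame = c(rep(1L, n_lame), rep(0L, n - n_lame)),
    parity = sample(seq(params$parity_range[1], params$parity_range[2]),
                    n, replace = TRUE),
    dim = sample(seq(params$dim_range[1], params$dim_range[2]),
                 n, replace = TRUE),
    yield = round(stats::rnorm(n, params$yield_mean, params$yield_sd), 1),
    stringsAsFactors = FALSE
  )

  dt <- 1 / params$rate
  slots_per_day <- as.integer(round(24 * 3600 * params$rate))
  n_slots <- slots_per_day * params$n_days
  slot_sec <- (seq_len(n_slots) - 1) * dt
  tod_min <- (slot_sec %% 86400) / 60
  milk <- rep(FALSE, n_slots)
  for (s in params$milking$start_min) {
    e <- s + params$milking$duration_min
    milk <- milk | (tod_min >= s & tod_min < e)
    if (e > 1440) milk <- milk | (tod_min < e - 1440)
  }
  emit_sec <- slot_sec[!milk]
  day_of <- floor(emit_sec / 86400) + 1
  timestamps <- params$start + emit_sec

  cow_frames <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed((params$seed + 7919L * i) %% .Machine$integer.max)
    prof <- effect_profile(metadata[i, ], params)
    # state probabilities are *time shares*; segment-selection weights are
    # share / mean dwell so that expected occupancy matches the shares
    dwell_sec <- params$dwell_mean * 60
    seg_p <- prof$probs / dwell_sec
    seg_p <- seg_p / sum(seg_p)
    ss <- draw_state_sequence(emit_sec, params$n_days * 86400,
                              seg_p, dwell_sec)
    # daily anchor per state, jittered around the zone centre with the
    # parity-driven x shift, clamped inside the zone
    nst <- length(SIM_STATES)
    cow_jit <- stats::rlnorm(1, 0, params$jitter_cow_cv)
    ax <- matrix(0, nst, params$n_days); ay <- ax
    for (s in seq_len(nst)) {
      z <- zones[[SIM_STATES[s]]]
      cx <- (z["xmin"] + z["xmax"]) / 2 + prof$anchor_shift_x -
        params$parity_effect * mean(params$parity_range)
      cy <- (z["ymin"] + z["ymax"]) / 2
      jsd <- prof$jitter_sd[SIM_STATES[s]] * cow_jit
      ax[s, ] <- pmin(pmax(cx + stats::rnorm(params$n_days, 0, jsd),
                           z["xmin"] + 0.25), z["xmax"] - 0.25)
      ay[s, ] <- pmin(pmax(cy + stats::rnorm(params$n_days, 0, jsd),
                           z["ymin"] + 0.25), z["ymax"] - 0.25)
    }
    m <- length(emit_sec)
    # within-segment free walk, then fold into the wander box
    seg <- ss$segment
    new_seg <- c(TRUE, seg[-1] != seg[-m])
    step_x <- stats::rnorm(m, 0, params$step_sd)
    step_y <- stats::rnorm(m, 0, params$step_sd)
    step_x[new_seg] <- 0; step_y[new_seg] <- 0
    walk_x <- stats::ave(step_x, seg, FUN = cumsum)
    walk_y <- stats::ave(step_y, seg, FUN = cumsum)
    st <- ss$state
    anch_x <- ax[cbind(st, day_of)]
    anch_y <- ay[cbind(st, day_of)]
    zlim <- vapply(zones, identity, numeric(4))[, SIM_STATES]  # 4 x nst
    lo_x <- pmax(anch_x - prof$radius, zlim["xmin", st])
    hi_x <- pmin(anch_x + prof$radius, zlim["xmax", st])
    lo_y <- pmax(anch_y - prof$radius, zlim["ymin", st])
    hi_y <- pmin(anch_y + prof$radius, zlim["ymax", st])
    x <- reflect_into(anch_x + walk_x, lo_x, hi_x)
    y <- reflect_into(anch_y + walk_y, lo_y, hi_y)
    if (params$noise_sd > 0) {
      x <- x + stats::rnorm(m, 0, params$noise_sd)
      y <- y + stats::rnorm(m, 0, params$noise_sd)
    }
    cow_frames[[i]] <- data.frame(cow_id = ids[i], timestamp = timestamps,
                                  x = x, y = y, stringsAsFactors = FALSE)
  }
  locations <- do.call(rbind, cow_frames)
  rownames(locations) <- NULL
  list(locations = locations, metadata = metadata)
}

#' Write / read herd metadata
#'
#' Delimited text with header `cow_id,lame,parity,dim,yield`.
#'
#' @param metadata Metadata data.frame.
#' @param path File path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          stringsAsFactors = FALSE,
                          colClasses = c(cow_id = "character"))
  need <- c("cow_id", "lame", "parity", "dim")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metadata file is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(df$lame %in% c(0, 1))) stop("lame must be binary 0/1")
  df
}
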