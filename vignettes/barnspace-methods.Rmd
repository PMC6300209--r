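---
title: "Space-use and site-fidelity analysis of barn-housed dairy cows: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-use and site-fidelity analysis of barn-housed dairy cows: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barnspace)
```

## The problem

Lameness in dairy cattle is routinely under-detected; mobility scoring by
expert observers is accurate but labour-intensive. Indoor real-time
location systems (RTLS) record each cow's position continuously, so if
lame cows *use the barn differently* — feed less, rest more, cover a
smaller area, return to the same stall day after day — those patterns are
a candidate automated health indicator. `barnspace` implements the full
analysis chain from raw positional fixes to a lameness classifier, plus a
synthetic herd generator so that every stage can be tested without farm
data.

## Pipeline and model

### Trajectory preparation

Raw fixes `(cow, t, x, y)` are smoothed with a centred simple moving
average (default 15 samples = 2 minutes at 0.125 Hz; edges truncate to
the available samples, which avoids phase lag and keeps the stream length
fixed). Samples recorded during the three scheduled milking absences
(05:00, 13:00, 21:00, 90 min each — duration configurable because barn
routines only approximate it) and samples placed outside the barn
rectangle by sensor error are then removed, with per-reason counts so
that `input = retained + excluded` is auditable at every stage.
Smoothing precedes cleaning by default (the alternative order is a
config switch). Days are cut at local midnight. Recording gaps are left
as missing time; the utilisation distribution below is count-based, so
interpolation would manufacture data.

### Utilisation distributions and ranges

Each cow-day's retained positions are binned on a fixed 40 × 13 grid of
1.5 m cells over the upper barn (x ∈ [0, 60], y ∈ [10, 30]); counts are
normalised to a discrete probability distribution U(q). Thirteen 1.5 m
rows cover only 19.5 m of the 20 m depth; the residual 0.5 m strip is
merged into the top row so no in-barn point is unbinned. The *k%
isopleth* is the smallest set of highest-mass cells whose cumulative mass
reaches k/100: cells are sorted by mass (ties broken by row-major index;
an include-all-ties mode exists) and the crossing cell is included. The
95% isopleth is the full range, the 50% isopleth the core range, both
measured in cells. Zone occupancies are sums of cell masses whose
*centres* fall in the zone rectangle; rectangles are half-open so every
cell belongs to exactly one zone.

### Site fidelity

Day-to-day consistency is the Bhattacharyya affinity between daily
distributions,

$$O_{t_1 t_2} = \sum_{q} \sqrt{U_{t_1}(q)\, U_{t_2}(q)},$$

which is 1 iff the distributions coincide and 0 iff their supports are
disjoint. (The plain product $\sum U_1 U_2$ is sometimes written for
this coefficient, but it does not attain 1 at full overlap except for
point masses; the affinity form is the default and the product form is
available behind a flag for comparison.) The per-cow score averages the
coefficient over consecutive day pairs; all-pairs and distance-weighted
(weight 1/|i−j|) variants are provided as robustness checks. The six
fidelity measures S11–S16 combine three regions (whole barn, feeding
area F, cubicle area C_T) with two isopleth levels (95%, 50%): each
daily distribution is **restricted to the region first, then truncated**
at the isopleth of the restricted distribution and renormalised. The
order matters (a regression test pins it): truncating first can delete a
region's minor cells before the region is even considered. Days on which
a cow never enters the region are dropped from the pair average and the
number of usable pairs is reported.

### The sixteen measures

S1 distance moved per hour (gap-bridging steps over 40 s are excluded
from both distance and duration); S2/S3 mean x and y; S4–S8 occupancy of
F, C_T, C1–C3; S9/S10 mean daily full/core range sizes; S11–S16 the
fidelity battery. Daily values are averaged over available days.

### Model screen

Each measure is regressed on lameness L (binary), parity P and days in
milk D over **all hierarchical term sets** (interactions only with their
margins present — 19 models for three predictors); mean daily yield is
accepted as an optional fourth predictor but is off by default, and
'day' is never a predictor. Models are ranked by
$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$ with k counting intercept, slopes
and the Gaussian error variance. The selected model is reported with its
F test against the intercept-only model, coefficient t tests,
Shapiro–Wilk residual normality, the Cook–Weisberg score (NCV) test of
variance against fitted values, and VIFs (1/(1−R²) of each predictor on
the others, flag at 10). If normality is rejected at 5%, the observation
with the largest absolute studentized residual is removed and the model
refit, up to two removals (configurable), mirroring the manual outlier
handling such studies apply; named force-removal is also supported for
exact replication of a published fit.

### Lameness classifier

A logistic model $\log(p/(1-p)) = \beta_0 + \sum_i \beta_i S_i$ is fitted
by maximum likelihood for every subset (size ≤ 3 by default) of the
measures whose selected linear model had a significant non-intercept
coefficient — restricting the pool this way limits overfitting at n = 20.
Subsets are ranked by AICc with k = number of coefficients (binomial
likelihood; no dispersion parameter). Classification uses p ≥ 0.5, ties
to lame. Complete or quasi-separation is detected (exploding
coefficients / fitted probabilities at 0 or 1) and flagged rather than
ranked as a trustworthy likelihood. In-sample accuracy is the headline
metric to match the study design; leave-one-out accuracy is also
reported, clearly an extension.

## The synthetic herd

The generator is a continuous-time semi-Markov process over five
behavioural states (FEED, three cubicle blocks, PASSAGE) with
exponential dwell times; within a dwell the cow performs a reflected
random walk around a per-zone daily anchor, confined to the zone; an
isotropic Gaussian error (σ = 1 m, consistent with an RTLS validated to
95% of fixes within 2 m) is added afterwards. Milking absences are
*deleted* samples — the analysis discards those windows anyway. State
probabilities are specified as **time shares** (segment draws are
weighted by share/dwell), so configured occupancies are what the
measures estimate.

Defaults describe the study design the package targets: 20 cows, half
lame, 5 days at 0.125 Hz, parity uniform on 1–6, days in milk uniform on
44–220, yield ~ N(42.5, 6.9) litres/day (carried but unused, as in the
study). Lameness effects are the three canonical ones: −0.062 on the
FEED share, +0.056 on the cubicle share, and ×0.8 on the wander radius.
Parity shifts every anchor by +3 m in x per unit (toward the parlour
passage); days in milk scales the radius by +0.15%/day about its
reference (125 d) for non-lame cows, with the sign flipped for lame cows
(the lameness-by-DIM interaction). Dwell means (18 min feeding, 36 min
cubicle, 5 min passage) were chosen once so the between-cow SD of the
feeding share (~0.05) matches the residual spread such field data show;
the wander radius (6.5 m) likewise puts the mean full range near 150–165
cells with a lame deficit of ~15 cells. Day-to-day anchor redraw
(SD 2.5 m, with per-cow lognormal variability) drives site fidelity; its
lame multipliers (`lame_jitter_mult`, `lame_feed_jitter_mult`) default
to neutral, because the canonical effect set does not include a fidelity
effect — setting them below/above 1 produces the higher-cubicle-fidelity
/ lower-feeding-fidelity patterns reported for lame cows, and the test
suite exercises both.

**What a green test does and does not establish.** The generator
reproduces zone-structured occupancy, milking absences, sensor noise and
the direction and rough magnitude of the lameness/parity/DIM effects. It
does not reproduce: social behaviour (queueing, displacement at the feed
face), post-milking feeding bouts or any within-day rhythm (a schedule
hook exists but defaults are time-homogeneous), gait differences, or the
extreme resting concentration of real cows — simulated core ranges
(~45 cells) are larger than the ~14 cells real herds show, because a
reflected walk fills its box far more evenly than a cow fills a stall.
Recovery tests on this world therefore validate the *statistical
machinery*, not any biological claim.

## Numerical choices

* Isopleth threshold: the crossing cell is included; ties break by cell
  index (deterministic); `include_ties` includes the whole tie class.
* UD sums are validated to 1 within 1e-9; Bhattacharyya values are
  clipped to [0, 1] against floating-point overshoot.
* Empty cow-days, zero-mass region restrictions and sub-minimum sample
  counts are flagged and propagated, never silently averaged as zeros.
* AICc is skipped (with a warning) when n ≤ k + 1.
* Per-cow simulation streams derive from `seed + 7919 · cow`, so herds
  are reproducible and cows independent; the caller's RNG state is
  restored afterwards.

## Known limitations

* With n = 20 the AICc subset ranking of the classifier is unstable
  among near-collinear measures. In the simulated world the FEED-share
  shift makes the cubicle share (S5) an informational mirror of the
  feeding share (S4), and one radius multiplier drives full and core
  range (S9, S10) together, so the top-ranked subset frequently names a
  mirror rather than S4/S9 themselves. The acceptance suite records this
  honestly: the subset-recovery expectation fails at the stated
  threshold while the mirror-counting rate is high.
* The generative family cannot produce opposite-signed lameness effects
  on the full and core range simultaneously, as observational data have
  shown; both respond to the single wander radius.
* The NCV test is implemented against fitted values (the common
  Cook–Weisberg form); testing against an arbitrary variance model is
  out of scope.
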