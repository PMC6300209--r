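# barnspace

Space-use and site-fidelity analysis for barn-housed dairy cattle tracked
with an indoor real-time location system (RTLS).

Lameness changes how a cow uses her barn: lame cows tend to spend less
time at the feed face, more time lying in the cubicles, cover a smaller
area, and return to the same spots day after day. `barnspace` turns raw
positional fixes into a per-cow panel of sixteen space-use and
site-fidelity measures, screens them against lameness, parity and
days-in-milk with exhaustive AICc model selection, and fits an
AICc-selected logistic classifier of lameness status. A synthetic-herd
simulator with the same statistical structure makes the whole pipeline
testable without farm data.

## The statistics in brief

* **Utilisation distribution (UD).** Each cow-day's smoothed, cleaned
  positions are binned on a 40 × 13 grid of 1.5 m cells over the upper
  barn and normalised: `U(q)` is the share of the day spent in cell `q`.
* **Core / full range.** The 50% (core) and 95% (full) isopleths are the
  smallest sets of highest-mass cells whose cumulative mass reaches the
  level; range size is their cell count.
* **Site fidelity.** Day-to-day overlap is the Bhattacharyya affinity
  `O = Σ_q √(U₁(q)·U₂(q))` ∈ [0, 1], averaged over consecutive day
  pairs, computed for the whole barn, the feeding area and the cubicle
  area at both isopleth levels (measures S11–S16).
* **Screen.** Each measure S_i is regressed on lameness `L`, parity `P`
  and days in milk `D` over all hierarchical term sets; models are
  ranked by small-sample-corrected AIC (`AICc`), with F tests,
  Shapiro–Wilk and non-constant-variance diagnostics, VIFs, and an
  automated studentized-residual outlier protocol.
* **Classifier.** `log(p/(1−p)) = β₀ + Σ β_i S_i` over all subsets
  (size ≤ 3) of the measures found significant in the screen, ranked by
  AICc, reporting in-sample (and leave-one-out) classification.

## Worked example

```r
library(barnspace)

herd     <- generate_herd(sim_params(seed = 1))      # 20 cows, 5 days, 0.125 Hz
features <- build_feature_table(herd$locations, barn_geometry())
report   <- screen_all(features, herd$metadata)
print(report)
#> Model screen: 16 responses
#> VIF: L = 1.054, P = 1.164, D = 1.108
#>
#>    response       terms  n   aicc       f_p significant
#> 3        S3           L 20  28.63 2.522e-04        TRUE
#> 4        S4           L 19 -70.57 5.437e-04        TRUE
#> 5        S5           L 20 -72.96 5.966e-05        TRUE
#> 9        S9   L+P+D+L:D 20 158.53 1.344e-06        TRUE
#> 10      S10   L+P+D+L:D 20 112.34 1.123e-06        TRUE
#> ...

ranking <- select_logistic(features, herd$metadata,
                           candidate_features(report))
print(ranking)
#> Lameness classifier ranking (AICc ascending):
#>    subset  aicc correct  n misclassified separated
#> 1      S5 12.11      18 20     1009;1020     FALSE
#> 2   S5+S9 14.26      18 20     1009;1020     FALSE
#> ...
```

Reading this: the screen finds lameness significant for the feeding-area
share (S4, negative), the cubicle share (S5, positive) and — through an
interaction with days in milk — the range sizes (S9, S10), with VIFs far
below the collinearity threshold of 10. The classifier then predicts
each cow's lameness status from small subsets of those measures; here
the best model classifies 18 of 20 cows correctly in-sample, using the
cubicle share (the mirror image of feeding time — on simulated herds the
AICc ranking picks freely among such near-collinear mirrors).

The same pipeline runs from files (`cow_id,timestamp,x,y` locations and
`cow_id,lame,parity,dim,yield` metadata) via `run_study()` or the CLI:

```sh
inst/scripts/barnspace simulate --out-dir out --seed 7
inst/scripts/barnspace run --config config.yaml
```

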