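# e2sfca

Block-level spatial accessibility of primary care, for health
geographers and service planners who need to know **where walking-range
clinic capacity is thin** — e.g. general-practitioner access for
elderly residents of dense public housing, where the unit of demand is
a single apartment block.

The package implements the enhanced two-step floating catchment area
(E2SFCA) method with a Gaussian distance decay inside a hard catchment,
followed by Getis-Ord Gi\* hot/cold-spot detection with 90/95/99%
confidence bins, a seeded synthetic-city generator for validation,
plain-text/GeoJSON IO with planning-area labelling, and a reproducible
pipeline with a run manifest.

## The model

Step 1 — each clinic *j* (capacity *S<sub>j</sub>*, default 1) gets a
provider-to-population ratio against the decay-weighted population in
its catchment:

> *R<sub>j</sub>* = *S<sub>j</sub>* / Σ<sub>k: d<sub>kj</sub> ≤ d₀</sub> *P<sub>k</sub>* *W*(*d<sub>kj</sub>*)

Step 2 — each block *i* sums the ratios of clinics it can reach:

> *A<sub>i</sub>* = Σ<sub>j: d<sub>ij</sub> ≤ d₀</sub> *R<sub>j</sub>*

with *W*(*d*) = exp(−*d*²/β²), β = *d₀*/2, and *W* ≡ 0 beyond *d₀*.
The default *d₀* = 400 m comes from an elderly walking-capacity
interval of 560 ± 105 m: lower endpoint 455 m, rounded down to 400 m
because straight-line distances understate street routes
(`derive_threshold(560, 105, 100)`). Gi\* z-scores on the resulting
surface mark statistically significant clusters of high (hot) and low
(cold) accessibility. See `vignette("accessibility-methods")` for the
full model, conventions and design choices.

## Worked example

Three blocks, two single-doctor clinics:

```r
library(e2sfca)
library(tibble)

blocks <- tibble(
  id = c("blk_a", "blk_b", "blk_c"),
  x = c(0, 250, 900), y = c(0, 100, 0),   # planar metres
  population = c(120, 80, 60))             # elderly per block
clinics <- tibble(id = c("gp_1", "gp_2"), x = c(50, 300), y = c(0, 0))

fit <- e2sfca(blocks, clinics)
fit$ratios
#> # A tibble: 2 × 4
#>   supply_id capacity weighted_demand   ratio
#>   <chr>        <dbl>           <dbl>   <dbl>
#> 1 gp_1             1           136.  0.00737
#> 2 gp_2             1            71.2 0.0140
tidy(fit)
#> # A tibble: 3 × 5
#>   id        x     y population a_index
#>   <chr> <dbl> <dbl>      <dbl>   <dbl>
#> 1 blk_a     0     0        120  0.0214
#> 2 blk_b   250   100         80  0.0214
#> 3 blk_c   900     0         60  0
```

`gp_1` serves 136 decay-weighted residents (both nearby blocks), so
each of its providers is shared 136 ways (ratio 0.00737); `gp_2` sits
farther from the heavy block and serves 71.2 (ratio 0.0140). Blocks a
and b reach both clinics, so their index is the sum 0.0214 — about 2.1
providers per 100 weighted residents; block c is more than 400 m from
any clinic and scores 0.

Hot-spot detection on a synthetic city with a planted high-supply town
(clinic intensity × 4) and a planted low-supply town (× 0.1):

```r
city <- generate_scenario(synthetic_scenario(seed = 1))
hs <- hotspot(e2sfca(city$demand, city$supply))
hs
#> <gi_star_result> 360 points, band = 884.497 m
#>   hot: 86 (>=90%), cold: 78, not significant: 196
evaluate_recovery(hs, city$truth, confidence = 95)
#> # A tibble: 2 × 7
#>   class n_truth n_detected n_correct precision recall false_rate_neutral
#>   <chr>   <int>      <int>     <int>     <dbl>  <dbl>              <dbl>
#> 1 hot        56         82        51     0.622  0.911             0.122
#> 2 cold       49         50        46     0.92   0.939             0.0157
```

91% of blocks in the planted high-supply disk are flagged hot and 94%
of the low-supply disk cold at ≥ 95% confidence. `autoplot(hs)` draws
the classic blue-to-red hot-spot map; `tidy(hs)` and
`hotspot_summary(hs)` give the per-block and per-area tables.

A whole run — simulate (or read), accessibility, hot spots, per-area
summary, manifest with parameter echo and file hashes:

```r
run_pipeline(run_config(scenario = list(), out_dir = "run1", seed = 1))
```

or from a shell via the bundled thin wrapper:

```sh
Rscript inst/cli/e2sfca.R run --out-dir run1 --seed 1
```

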