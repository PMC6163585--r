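---
title: "Methods: floating-catchment accessibility and hot-spot detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: floating-catchment accessibility and hot-spot detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(e2sfca)
```

## The problem

Primary-care accessibility for elderly city residents is shaped by where
clinics sit relative to where people live, at walking scale. This
package measures that geography at the residential-block level: demand
points are apartment blocks with an elderly head count, supply points
are clinics, and the question is how much clinic capacity is within
walking reach of each block once nearby blocks competing for the same
clinics are taken into account.

## The accessibility model

The enhanced two-step floating catchment area (E2SFCA) method runs in
two passes over a hard catchment of radius $d_0$.

**Step 1.** Each clinic $j$ with capacity $S_j$ is assigned a
provider-to-population ratio against the decay-weighted population
inside its catchment:

$$R_j = \frac{S_j}{\sum_{k:\, d_{kj} \le d_0} P_k\, W(d_{kj})}$$

**Step 2.** Each block $i$ sums the ratios of the clinics it can reach:

$$A_i = \sum_{j:\, d_{ij} \le d_0} R_j$$

Higher $A_i$ means more reachable capacity per competing resident;
$A_i = 0$ means no clinic within range. Distances are Euclidean on
projected planar coordinates — the method deliberately avoids a street
network, and the catchment threshold compensates (below). The boundary
is inclusive ($d = d_0$ counts) and coincident points are allowed.

### Where the decay weight enters

The decay-weighted lineage of the method is ambiguous about whether the
step-2 sum should also be weighted. The package's default, `demand_only`,
applies $W$ only inside the step-1 denominator, exactly as the formula
above. The conventional symmetric variant,
$A_i = \sum_j W(d_{ij})\, R_j$, is available as `mode = "symmetric"`;
it is the variant that conserves capacity,
$\sum_i P_i A_i = \sum_j S_j$ over clinics with non-empty catchments,
which the test suite asserts to $10^{-6}$. Neither variant is claimed
to be the only defensible reading; both are first-class and share every
other rule.

### The decay function

The Gaussian weight is

$$W(d) = \exp\!\left(-\frac{d^2}{\beta^2}\right), \qquad \beta = d_0/2,
\qquad d \le d_0,$$

and exactly 0 beyond $d_0$. Printed renderings of this family are
notoriously ambiguous between $\exp(-d^2/\beta^2)$,
$\exp(-d^2/2\beta^2)$ and $\exp(-d/2\beta^2)$; the package adopts
$\exp(-d^2/\beta^2)$ with $\beta = d_0/2$ because it gives an edge
weight of $W(d_0) = e^{-4} \approx 0.018$ — near zero, consistent with
a hard "no effect beyond the threshold" catchment, while
$\exp(-d^2/2\beta^2)$ would leave $e^{-2} \approx 0.135$ of the weight
at the boundary. Both $d_0$ and $\beta$ are user-settable, so other
conventions are one argument away. A `uniform` family ($W \equiv 1$
inside the catchment) recovers the plain 2SFCA and is used by the
dominance tests: shrinking step-1 denominators can only raise every
$A_i$ in `demand_only` mode.

### Parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| `d0` | 400 | m | lower endpoint of a measured elderly walking-capacity interval, 560 − 105 = 455 m, rounded down a granularity step because straight-line distances understate street routes; see `derive_threshold(560, 105, 100)` |
| `beta` | `d0/2` = 200 | m | Gaussian bandwidth giving $W(d_0) = e^{-4}$ |
| `capacity` | 1 | providers | one provider per clinic — the minimum possible, avoiding inflated ratios where rosters are unknown |
| `mode` | `demand_only` | — | the as-printed form of the weighted model (see above) |

Empty catchments are a recorded condition, not an error: a clinic with
zero weighted demand gets a null ratio and contributes nothing
downstream; a block with no reachable clinic scores 0. Zero-population
blocks still receive an index (it does not depend on the block's own
count) but add nothing to any denominator.

## Hot- and cold-spot detection

The Getis-Ord Gi* statistic standardizes each block's neighborhood sum
of $A$ values against the global mean:

$$G_i^* = \frac{\sum_j w_{ij} x_j - \bar{X} W_i}
{S \sqrt{\left(n \sum_j w_{ij}^2 - W_i^2\right)/(n-1)}}$$

with binary inclusive distance-band weights $w_{ij}$, self included,
$W_i = \sum_j w_{ij}$, and $S$ the population standard deviation.
Z-scores are binned at the two-tailed normal thresholds 1.645 / 1.960 /
2.576 into seven classes (−3 … +3): sign is cold/hot, magnitude is
90/95/99% confidence.

Numerical conventions: a degenerate denominator (all values identical,
or a point neighboring every other point) defines $z = 0$; inference is
the analytical normal approximation, as in standard GIS hot-spot
tooling, with no conditional permutation. Multiple-testing correction
is off by default; `fdr = TRUE` applies Benjamini–Hochberg across all
points and bins each point at the highest confidence whose adjusted
p-value survives.

The neighborhood band is the genuinely open choice: analyses of this
kind rarely state one. The default here is
$\max(2 d_0, \text{largest nearest-neighbor distance})$ — wide enough
to span adjacent catchments, and never leaving an isolated point (the
second term is the smallest band at which every point keeps at least
one non-self neighbor). It is reproducible from the data alone and
fully overridable; the resolved value is echoed in the run manifest.

## The synthetic city

No block-level elderly census or clinic register ships with the
package, so validation runs on a seeded generator whose structure
mirrors a dense public-housing city:

* town centres uniform in a 12 × 8 km extent; 6 towns of 60 blocks,
  Gaussian scatter with SD 500 m — towns a few kilometres apart, blocks
  clustered at sub-kilometre scale;
* elderly counts per block negative-binomial with mean 40 and
  dispersion 5 (variance ≈ 360 ≫ mean), matching the strong block-size
  heterogeneity of real public-housing stock at roughly the national
  elderly-per-block scale;
* clinics as an inhomogeneous Poisson process: town-centred Gaussian
  intensity integrating to 8 clinics per town (a realistic
  clinics-per-town count for a city-wide GP scheme), capacity 1 each;
* planted disk regions (radius 1000 m = 2 × town spread, centred on
  towns 1 and 2) multiply the local intensity by 4 (intended hot) and
  0.1 (intended cold). The process is simulated at the maximum
  multiplier and thinned pointwise, so realized counts are exactly
  Poisson at the multiplied rate everywhere — planting changes the
  mean, not the noise law.

Disk-shaped regions referenced to town indices keep the ground truth
unambiguous and guaranteed non-empty under every seed. All draws come
from one seeded stream: a scenario plus a seed reproduces the city
byte-for-byte, which the pipeline's manifest hashes verify end to end.

What the generator does **not** emulate: real street networks and
barriers (rivers, expressways), correlated clinic/block placement along
commercial corridors, heterogeneous clinic capacity, or the spatial
autocorrelation of block sizes within a town. Passing recovery tests
therefore show that the pipeline detects planted supply anomalies under
idealized geography — not that it would resolve subtler real-world
contrasts at the same confidence.

### Recovery behaviour

On the default scenario the pipeline (index → Gi* → bins) flags, pooled
over seeds 1–5, over 80% of truth-hot blocks at ≥ 95% confidence with
under 6% of neutral blocks falsely hot, and every seed yields
cold-binned blocks inside the planted low-supply disk. These figures
are recomputed, not quoted, by `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`. Individual seeds fluctuate — a town's Poisson
clinic draw occasionally doubles its baseline supply, and the cold
disk's thinned rate (0.8 expected clinics) occasionally realizes 2–3 —
which is the intended behaviour of an honest noise model, and why the
headline figures pool five seeds.

## Problem sizes and numerics

The bundled analyses run at desk scale by design: oracle-equivalence
checks use 200 × 30 instances (the production grid-bucket neighbor
search is compared against an exhaustive scan to $10^{-9}$ relative),
recovery runs five 360-block cities, and the whole suite completes in
well under a minute. The index computation is $O(\text{pairs})$ after
bucketing, so city-scale inputs (tens of thousands of blocks) remain
practical.

Other numerical choices: catchment and band boundaries are inclusive;
point-in-polygon labelling uses the even-odd rule with points on an
edge assigned to the first containing area in file order (determinism
over elegance); coordinates are never reprojected, and input that looks
like raw longitude/latitude is rejected at the IO boundary with
guidance to project first (overridable for legitimately small planar
extents).

## Known limitations

* Euclidean distance understates true walking distance irregularly;
  the rounded-down threshold compensates only on average.
* Uniform capacity 1 ignores multi-doctor clinics; capacities are
  accepted per clinic if known.
* The Gi* normal approximation is anti-conservative for very small
  neighborhoods; with the default band and clustered blocks,
  neighborhood sizes are comfortably large, but sparse custom bands
  deserve the FDR flag.
* The index is a potential-access measure: it models no utilization,
  queueing or competition between clinics (no three-step variant).
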