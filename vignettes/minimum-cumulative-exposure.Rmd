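---
title: "Least-cost climate trajectories: velocity, minimum cumulative exposure, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost climate trajectories: velocity, minimum cumulative exposure, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climExposure)
```

## The model

Distance-based climate velocity asks how fast an organism must move to keep
the climate it experiences constant: the distance from a source pixel to a
climate analogue in the future period, divided by the elapsed time. This
package implements the least-cost refinement of that idea. The working
assumption is that organisms follow the path that minimises their exposure
to dissimilar climates, not the straight line; the straight-line (ED)
metric is retained as the baseline for comparison.

For a source pixel with rounded current temperature $T$ (its *increment*):

1. **Analogues.** Future-period pixels within $\pm h$ of $T$ ($h$ = 0.25 °C
   by default, i.e. a 0.5 °C bin). The bin is deliberately wider than the
   0.1 °C increment spacing so that 4.9 °C and 5.1 °C pixels are analogues
   of the 5.0 °C increment instead of separate classes.
2. **Cost surface.** Each pixel $i$ gets an integer dissimilarity cost:
   1 within the analogue bin, then one more per further band of one bin
   width — the banded form of $\mathrm{cost}_i = P\,|T - T_i| + 1$ with
   $P = 2$ per °C. Adding 1 keeps costs positive and makes cost equal
   distance on analogue terrain, which the MCE formula exploits.
3. **Temporal composite.** The climate moves while the organism does. The
   cost surface is therefore the elementwise *minimum* of the banded cost
   over $n$ temperature fields linearly interpolated between the current
   and future grids: a pixel that warms through $T$ at any point during the
   interval is charged as an analogue. This also guarantees the destination
   (an analogue *of the future grid*, the last series member) costs 1, so a
   trajectory that tracks the moving isotherm accrues no spurious exposure.
   Without the composite, MCE would be positive even for a pixel drifting
   poleward over perfectly flat terrain.
4. **Routing.** Exact Dijkstra over the 8-connected (optionally
   4-connected) lattice of non-nodata pixels. The edge between adjacent
   pixels $a,b$ weighs $\frac{\mathrm{cost}_a + \mathrm{cost}_b}{2}\,
   \ell_{ab}$, with $\ell_{ab}$ the pixel size for cardinal moves and
   $\sqrt 2$ times it for diagonal moves. The destination is the analogue
   with the least accumulated cost.
5. **Metrics.** The extracted path assigns each pixel half of each incident
   path edge ($l_i$; endpoints carry one half-edge), so
   $\sum_i l_i = \mathrm{MED}$ and
   $\sum_i \mathrm{cost}_i\, l_i = \text{accumulated cost}$ hold exactly.
   Then $\mathrm{velocity} = \mathrm{distance}/\mathrm{time}$ and
   $$\mathrm{MCE} = \frac{\sum_{s \to d} \mathrm{cost}_i\, l_i -
   \mathrm{MED}}{p},$$
   the °C-weighted dissimilarity the best possible route could not avoid.
   MCE is invariant to how much *analogue* terrain the path crosses: only
   excursions above cost 1 contribute.

A **forward** run (sources on the current grid) measures exposure; a
**reverse** run measures accessibility — whether the climates that will
occupy a site can get there. Reverse mode is defined here as a strict role
swap: sources are future-grid pixels, analogue sets come from the current
grid, and the interpolated series runs future → current through the same
composite machinery. The literature describes reverse velocity without
procedural detail at this level, so the swap is declared rather than
inferred.

## Parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `halfWidth` | 0.25 | °C | analogue bin half-width; bin = 0.5 °C |
| `incrementStep` | 0.1 | °C | one routing problem per distinct rounded value |
| `penalty` | 2 | per °C | one cost unit per 0.5 °C band; converts cost back to °C in MCE |
| `waterCost` | 5000 | — | far above any achievable land cost (land costs stay ≈ 1–100 for realistic temperature ranges), so water is crossed only when no land route exists |
| `nSteps` | 31 | — | ≈ 3-year increments over 90 years |
| `elapsedTime` | 90 | yr | midpoint-to-midpoint of 1981–2010 vs 2071–2100 normals |
| `neighbourhood` | 8 | — | matches common least-cost practice; 4 available |
| `islandPolicy` | exclude | — | see below |

## Numerical choices

- **Ingest rounding.** Temperatures are rounded to 0.1 °C half away from
  zero (not banker's rounding) when read or constructed, so increment and
  bin membership are reproducible across platforms. Interpolated
  intermediate grids are *not* re-rounded: the banded cost handles
  arbitrary precision, and re-rounding would manufacture bin-boundary
  artefacts mid-series.
- **Band boundaries.** Cost 1 iff $|T - T_i| \le h$ (the analogue
  definition is inclusive); each outer band is half-open with its *upper*
  edge inclusive, so a dissimilarity of exactly 0.75 °C falls in band 2.
  Comparisons carry a $10^{-9}$ tolerance because 0.1 °C steps are not
  exact binary fractions.
- **Tie-breaks.** Destination selection minimises accumulated cost, then
  Euclidean distance to the source, then row-major pixel order — fully
  deterministic, so identical inputs give bitwise-identical outputs.
- **Edge weights.** The arithmetic mean of endpoint costs times edge length
  is declared as the transition rule. Conductance-style means would break
  the exact accounting identity that the MCE subtraction of MED relies on;
  preserving that identity was treated as the binding constraint.
- **Degenerate cases.** A source that is its own analogue gets
  MED = ED = MCE = 0 and ratio 1; ratio is NA if ED = 0 with MED > 0
  (unreachable by construction, kept for safety). Sources whose analogue
  set is empty or entirely unreachable are flagged `noAnalogue` with NA
  metrics rather than dropped silently.
- **Islands.** Connected land components (same connectivity as routing)
  other than the largest are islands by default; a minimum-area rule is
  exposed as an alternative since no size threshold is canonical. With the
  default policy islands are removed from sources *and* analogue sets
  before routing, so destinations can never land on one; `flagIslands()`
  implements the source-or-destination exclusion rule for results computed
  with `islandPolicy = "keep"`. The classification median is computed after
  exclusion.
- **Geometric means** (sensitivity summaries) are taken over strictly
  positive values; zeros are excluded and counted (`nZero`) because the
  geometric mean is undefined at zero and the zero share is scientifically
  interesting in itself (it is the MCE = 0 fraction).

## The synthetic landscapes

The generators produce the study conditions for every test:

- **Flat gradient** — monotone north–south field, uniform warming. Emulates
  plains: ground truth is the analytic poleward displacement, and the
  correct outcome is MCE ≡ 0 with velocity_MED = velocity_ED. Note that
  the *nearest analogue-set member* sits $(w - h)/g$ pixels poleward (the
  bin edge), not $w/g$ (the exact match); tests assert the oracle-computed
  value. With the default 0.05 °C/px gradient, ingest rounding can shift
  the nearest analogue by one pixel at rows whose values fall on .x5 ties —
  tests use a brute-force analogue scan rather than the idealised formula.
- **Ridge/valley** — elevation profile × lapse rate, two plateau ridges
  around a warm valley of configurable width and dissimilarity. The second
  ridge is `warming` colder, so it holds the only analogues, and the
  least-cost path must cross the valley band: MCE has the closed form
  $(\mathrm{band} - 1) \cdot \mathrm{valleyWidth} \cdot
  \mathrm{pixelSize} / p$ (2.5 °C for one 5-km cost-2 pixel, 5.0 °C for
  two, at $p = 2$).
- **Peninsula** — a north-pointing land tongue flanked by water, a mainland
  band to the south, a single cold summit holding the tip's only future
  analogue, and a one-pixel bay island. Trajectories from the tip must run
  south through warmer rows (positive MCE, destination south of the
  source); the all-land control opens a cooler diagonal corridor and
  lowers the tip's MCE; the island exercises the exclusion rule.

Noise is off by default so that worked-example values are exact; when
requested it is seeded and deterministic. What these fixtures do *not*
emulate: realistic GCM spatial autocorrelation, multivariate climate,
coastline geometry at scale, or nonlinear warming trajectories. Passing
tests demonstrate the correctness of the machinery (routing, accounting,
composites, classification), not continental-scale results, which depend on
external gridded climate data.

## Problem sizes

The shipped tests and the acceptance script run entirely on grids between
5×5 and 50×50 pixels: large enough that routing is non-trivial (detours,
water crossings, island components) and small enough that a deliberately
naive $O(V^2)$ Dijkstra oracle can verify every accumulated-cost field
exactly (100 randomized grids up to 20×20, mixed 4- and 8-connectivity).
The full pipeline on a 30×10 flat-gradient pair completes in well under a
second; per-increment cost surfaces are built lazily, one routing problem
per distinct 0.1 °C value.

## Known limitations

- Planar distances in projected km; geographic (degree) grids are rejected
  rather than reprojected.
- Temperature only; no multivariate (e.g. temperature + precipitation)
  dissimilarity and no gradient-based velocity.
- Per-pixel trajectories are retained only on request; an all-pairs
  trajectory store at continental scale is out of scope.
- The resampling statistic for coarsening is the block mean; other
  statistics may be appropriate for some variables and are not offered.
- The temporal composite assumes a linear warming trend between the two
  periods; scenario-specific trajectories are not modelled.
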