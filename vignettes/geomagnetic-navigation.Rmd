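---
title: "Simulating geomagnetic navigation strategies with biased random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating geomagnetic navigation strategies with biased random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magnav)
```

## The question and the experiment

Migratory birds may read the Earth's magnetic field as a compass, as a map,
or as both. `magnav` implements a simulation experiment for confronting
candidate geomagnetic navigation strategies with observed migration tracks:
empirical hourly GPS trajectories supply a movement kernel (how the bird
moves), daily geomagnetic grids supply the environment (what the bird could
sense), and each candidate strategy is translated into a probability raster
(where the bird would prefer to go if it used that strategy). Biased
correlated random walks sample trajectories from the product of movement and
strategy preferences; the simulated tracks are then scored against the real
ones, and strategies are compared by how often their simulations appear in
the best-scoring decile.

The three cues are the total field intensity F (nT, roughly 24,000 nT near
the magnetic equator to 63,000 nT near the pole), the inclination I
(degrees; the dip angle, 0 at the magnetic equator, 90 at the pole) and the
horizontal component H = F cos I (nT). Declination plays no role in any
strategy here.

## Movement kernel

All animals' hourly steps are pooled into a joint histogram of (step
length, turning angle), with default 30 length bins on [0, L_max] and 24
angle bins on (-pi, pi]. To preserve the empirical autocorrelation of
consecutive steps, two lag-1 difference histograms (of step lengths, and of
turning angles wrapped to (-pi, pi]) are estimated within animals only, and
the sampling density of a candidate step is the product of the joint mass
and the two difference masses given the previous step. This product form is
the simplest composition that retains both the marginal structure and the
one-step persistence; a longer memory would sharpen geometric similarity at
considerable computational and interpretive cost.

At each simulated step the kernel is evaluated on the window of grid cells
within L_max of the current position (`movement_surface`); the strategy's
bias raster is evaluated on the same window; and the sampling distribution
is `movement^alpha * bias^beta` renormalised. The defaults alpha = 0.5 and
beta = 1 take the square root of the movement raster times the bias raster,
deliberately weighting the navigational signal above movement persistence
while keeping the empirical movement geometry. `beta = 0` switches any
strategy off and is exactly equivalent to the no-bias control (a property
the test-suite verifies with a two-sample KS test on ~10,000 steps). The
initial heading is the bearing to the best bias cell in reach plus a
uniform error on [-pi/12, pi/12].

Positions are drawn per cell and then jittered uniformly within the cell
(`jitter = "centre"` disables this for exact-reproducibility checks). A
radial clamp keeps every realised displacement at or below L_max, because
jitter on coarse cells could otherwise exceed the kernel's support.

## Strategy surfaces

* **No bias** - all cells 1 (the control).
* **Taxis** - linear rescaling of the day's cue grid so the global minimum
  has probability 1 and the maximum 0 (autumn runs from high to low
  geomagnetic values; a `towards = "max"` flag inverts this for spring).
* **Constant heading** - the compass reference is the cue's global extreme
  E (configured min or max); the optimum angle theta* is measured at the
  current position between the rays towards E and towards the target, and
  every cell is scored `1 - |angle - theta*| / 180` on its own vertex
  angle. theta* is recalibrated once per simulated day (the first of every
  24 steps), matching the biological evidence for daily compass
  calibration; the raster itself is rebuilt from the current position at
  every step. The vertex of the angle is the bird's position - the other
  reading (vertex at the extreme) is not implemented.
* **Bi-gradient map** - per cue, `1 - |v - v_target| / range(v)` clipped to
  [0, 1], using the raster's full daily range; the two single-cue rasters
  are multiplied. The cue pair is unordered.
* **Combination** - the single-cue gradient-to-target raster of the first
  cue multiplied by the constant-heading raster of the second cue (the
  ordered pairs give the six combination models; the heading component uses
  the minimum as its reference).

The full design enumerates 19 models: 1 no-bias, 3 taxis, 6 constant
heading (min/max x 3 cues), 3 bi-gradient pairs, 6 ordered combination
pairs. With 14 animals and 100 replicates this yields 1400 simulations per
model.

## Correlated random bridge

The bridge (CRB) is the correlated random walk (CRW) conditioned to end at
the empirical track's endpoint. Each cell is additionally weighted by a
normal density of the required per-step displacement
`d(cell, target) / (k - 1)` around the kernel's mean step length, with a
standard error shrinking as `1 / sqrt(k - 1)` over the k remaining steps;
the final position is set to the target exactly. Four numerical guards make
the endpoint reachable in practice, because a correlated walk cannot convert
every future step into net displacement and coarse cells add jitter noise:

1. cells requiring a faster sustained pace than
   `min(L_max - cell/2, mu + 0.5 sd)` per remaining step are infeasible
   (this sits inside the hard `(k - 1) L_max` bound);
2. once the walker is behind pace it may not lose further ground;
3. the pull may override cells where the movement kernel has zero mass via
   a 1e-6 floor on the movement weight - the endpoint is a hard constraint;
4. within-cell jitter reverts to the cell centre when it would exit the
   shrinking prism.

A replicate whose forced final hop would still exceed L_max aborts and is
redrawn on a fresh RNG substream (up to 50 attempts, all deterministic in
the batch seed). On the bundled scenarios fewer than 10% of bridge
replicates need a redraw.

## Scoring and evaluation

Three similarity measures compare each simulated track with its animal's
empirical track: mean pointwise distance (m), dynamic time warping (the
unnormalised accumulated Euclidean cost with symmetric unit-slope moves -
chosen because it is directly checkable against exhaustive warping-path
enumeration, and rank-preserving for the equal-length pairs used here), and
the dynamic interaction index (cosine of the heading difference times a
displacement-similarity factor, averaged over steps; zero displacements
contribute a factor 1 when shared and 0 when one-sided). DI lies in
[-1, 1].

Each measure is modelled against the model labels with a linear mixed model
(`lme4`, REML) with a per-animal random intercept; a singular fit falls
back to per-label means with animal-clustered standard errors, flagged in
the output. Per strategy family, the cue variant with the most favourable
estimate on a configurable reference measure (default: mean distance) is
retained; the five retained models are pooled and the best
`floor(0.10 N)` simulations per measure are tallied by strategy. With five
strategies, 20% per strategy is the no-information baseline. Ranking ties
break by a stable sort on (score, animal, replicate).

## Synthetic data: what it emulates and what it cannot show

Real inputs (Movebank tracks, daily magnetic model grids) are not bundled;
the `synthdata` module generates substitutes that preserve exactly the
features the method consumes.

The synthetic field is a planar monotone *pseudo-dipole*: F and I
interpolate radially from a pole point (63,000 nT, 90 degrees) to the
farthest grid corner (24,000 nT, 10 degrees), H = F cos I exactly, with a
daily drift of 10 nT/day and per-cell storm noise of sd 30 nT (truncated at
3 sd; the mid-latitude daily variation is of order 30-100 nT). Inclination
receives the proportionally scaled perturbation so the F/I/H relations stay
consistent. Field ranges by construction give a mean F gradient of order
10 nT per km across the domain diagonal. Synthetic tracks emulate autumn
goose migrations: hourly fixes along a pole-to-equator corridor at a mean
ground speed with per-fix heading noise (sd 0.25 rad) and 15% speed
variation, always exceeding the 1500-km length filter; in strategy mode the
tracks are instead simulated under a chosen strategy at bias weight 5 with
a corridor-estimated reference kernel.

Three sizes are bundled as named scenarios: `smoke` (3 animals, 24 h at
65 km/h, 60 x 60 grid of 30 km cells), `paper-scale` (14 animals, 72 h at
30 km/h, 100 x 100 grid of 25 km cells - the full design's animal count and
duration), and `recovery-taxis` (6 animals, 48 h at 40 km/h, 70 x 70 grid
of 30 km cells, tracks generated under taxis-on-F at bias weight 5). The
grids are coarser than the 5-km convention of real daily magnetic model
rasters so that whole-design batches stay tractable; all formulas are
resolution-agnostic.

Passing tests on these fixtures show that the machinery is correct - the
bookkeeping, the surface formulas, the bridge's endpoint contract, the
measure oracles, the null calibration at 20% per strategy. They do not show
that the method discriminates strategies on real data. Indeed the radial
pseudo-dipole is *degenerate* for strategy recovery: gradient descent on a
radial field is a straight ray, so the taxis direction coincides with the
straight line to the (self-fulfilled) endpoint of a taxis-generated track,
and the target-informed map strategies - which predict a wandering walk by
the chord to its known endpoint - are systematically closer in pointwise
distance than an independent draw of the generating taxis process. On this
field the top-decile modal strategy is therefore typically constant heading
or the combination even when the tracks were generated by taxis; real
fields, where reference tracks bend along gradients that do not aim at the
endpoint, are required for positive strategy identification. The test-suite
states this check and reports its failure honestly rather than weakening
it.

## Preprocessing defaults

Raw tracks are cleaned in a fixed order: exclusion zones (500 km around the
northernmost fix for the breeding area; 700 km around the southernmost and
westernmost fixes for the wintering area), then the 6 km/h ground-speed
filter (a fix survives if either adjacent segment is at least that fast),
then the 1500-km path-length filter, then linear interpolation to hourly
fixes. The source procedure does not state an order; this one removes the
seasonal clusters before speeds are judged, so slow flight onset inside the
corridor is preserved. Synthetic fixtures are already clean migrations, so
pipeline-level examples configure proportionately smaller zone radii - the
defaults assume raw tracks that include the seasonal residence clusters.

## Numerical conventions

Headings are mathematical angles (radians, counter-clockwise from +x),
wrapped to (-pi, pi] with -pi mapping to +pi. Grid origins are the centre
of the top-left cell, rows grow southwards, coordinates are planar metres;
point queries interpolate bilinearly between cell centres (nearest-cell
lookup is available). Histogram bins are uniform and left-closed with the
top edge included in the last bin; bin indices tolerate one-ulp boundary
noise. Extremum locations break ties by smallest (row, column). Batch
replicates run on substreams seeded by a deterministic 31-bit hash of
(animal, model label, replicate, attempt), so any subset of a batch can be
reproduced independently.

## Problem sizes used by the checks

The test-suite runs the full design's counting stage (7000 pooled
simulations of 72 steps plus the 8400-run constant-heading family) on the
`paper-scale` scenario, and the calibration checks (null at beta = 0,
recovery across 10 seeded repetitions, bridge flatness at 80 replicates,
weighting sweep at beta in {0, 1, 5} with 300 replicates per seed) on the
`recovery-taxis` scenario. `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.
```{r design, eval = TRUE}
length(enumerate_model_configs())
```
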