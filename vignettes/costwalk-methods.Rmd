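---
title: "Least-cost walks by cellular automata: model, geometry and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Least-cost walks by cellular automata: model, geometry and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(costwalk)
```

## The model

`costwalk` simulates the movement of an agent — a foraging group, a
dispersing population, any walker whose route is decided locally — across
a georeferenced cost (friction) surface such as terrain slope in degrees.
Unlike least-cost-path analysis, which assumes global knowledge of the
terrain between two known endpoints, the agent here knows only its
*decision catchment*: the single ring of cells around its current
location on a lattice overlaid on the cost raster. At each timestep $t$
the agent evaluates the aggregated cost $n_{ij}^t$ of every cell in that
ring and relocates to the minimum,

$$ ij^{\,t+1} = \arg\min\nolimits_{\text{ring}}\, n_{ij}^t , $$

a cellular-automata transition rule with two stochastic escape hatches:

* **ties** — when two or more candidate cells share the minimum, one is
  chosen uniformly at random;
* **visited-cell exclusion** — cells the agent has already occupied are
  removed from the candidate set, which prevents see-saw oscillation
  between two mutually-minimal cells; if *every* candidate has been
  visited, the agent falls back to a uniform random choice over the whole
  ring, and the event is flagged on the walk record.

A walk runs for `n_steps` timesteps or until no valid candidate remains
(`hit_edge`). Because the stochastic rules fire only occasionally, a walk
is nearly deterministic given the surface, but repeated seeded runs
explore the family of routes the terrain admits.

## Lattice geometry

Two ring shapes are supported (`neighbourhood_spec()`):

* **square (Moore)** — 8 candidates. Cell `(i, j)` (row, column, 0-based,
  north-up) has centre `anchor + ((j+0.5)·nsize, −(i+0.5)·nsize)`.
  Orthogonal steps have length `nsize`, diagonal steps `nsize·√2`, so
  square walks mix two step lengths.
* **hexagonal** — 6 candidates, pointy-top axial coordinates `(q, r)`
  with centre `x = nsize·(q + r/2)`, `y = −nsize·(√3/2)·r`. `nsize` is
  defined as the centre-to-centre spacing, so *every* hex step has length
  exactly `nsize` — the property that motivates hexagonal rings when
  comparing walk distances across directions.

The lattice anchor coincides with the raster origin, and the starting
cell is the lattice cell containing the start coordinate; both choices
make the world-to-lattice mapping a pure function of the inputs.

## Cost aggregation

When `nsize` exceeds the raster resolution, each neighbourhood cell
covers several raster values; its cost is their arithmetic mean
(`aggregate_cell_cost()`). Membership follows the *centre rule*: a raster
value belongs to the cell whose footprint contains the raster-cell
centre. For a 200 m cell over a 100 m raster this yields exactly
$200/100 \times 200/100 = 4$ members. The rule generalises cleanly to
hexagons and to `nsize` that is not an integer multiple of the
resolution, where area-weighted schemes would be markedly more complex
for little behavioural difference at these cell counts.

Numerical details worth knowing:

* Square footprints are half-open (west/north edges inclusive). Hex
  membership is nearest-centre, computed by cube-rounding fractional
  axial coordinates; when a raster centre falls *exactly* on a hex edge —
  which happens systematically when `nsize` and the resolution are
  commensurate, e.g. equal — the rounding rule resolves it
  deterministically, so results are reproducible bit-for-bit even in
  aligned configurations.
* NoData raster values are excluded from means; a cell with no valid
  member is invalid and leaves the candidate set, exactly like a cell
  whose footprint crosses the raster boundary.
* `nsize` below the resolution is permitted: a footprint containing no
  raster centre falls back to the raster value under the footprint
  centre, keeping the cost defined rather than leaving holes in the ring.
* Ties in the transition rule are declared within *relative tolerance
  1e-9*. Exact float comparison would make ties vanish on continuous
  surfaces even where the terrain is effectively flat; a relative
  tolerance recognises them at every cost scale.
* Neighbours whose footprint lies only partly outside the raster are
  excluded rather than terminal, so walks may hug the map edge; the walk
  ends only when the whole ring is invalid.

## Batches, seeding and the density raster

`run_batch()` repeats a configuration (`batch_config()`; the conventional
exploratory design is 100 walks of 1000 timesteps with random starts).
Each walk receives an independent substream seed derived affinely from
`(master_seed, walk index)`, so batches are bit-reproducible and
independent of execution order. Random starts are drawn by rejection —
uniform points in the extent, accepted when they land in a fully-interior
valid cell — which makes the start distribution exactly uniform over
valid cells.

The batch's aggregate layer (`density_raster()`) counts, per raster cell,
the number of **distinct walks** that crossed it (a walk increments a
cell at most once, however often it loops through). Each walk's polyline
of consecutive cell centres is rasterised with a supercover traversal —
every raster cell the segment passes through is marked, and a segment
crossing a grid corner exactly marks all four adjacent cells — so
large-`nsize` walks leave connected traces rather than strings of
isolated cells.

## Walk statistics

For each walk (`walk_distances()`):

* **total distance** — accumulated centre-to-centre path length;
* **resultant distance** — straight-line start-to-end distance;
* **walk deviation** — `100·(total − resultant)/total`, the percentage by
  which the walk departs from a straight line, comparable across
  neighbourhood sizes. A zero-length walk has deviation 0 by convention;
  the value is clamped to `[0, 100]` so floating rounding on a
  near-closed walk cannot exceed the bound.
* **azimuth** — the compass bearing of the resultant by the quadrant
  method: base angle `atan(|ΔE|/|ΔN|)` corrected per quadrant (NE θ,
  SE 180−θ, SW 180+θ, NW 360−θ), clockwise from grid north (the raster's
  +y; no convergence correction to true north is applied). Walks with
  zero displacement have no bearing and are excluded — never zero-filled
  — from circular analyses.

Sample-level orientation analysis:

* `rayleigh_test()` — circular uniformity against a unimodal
  alternative; statistic `Z = n·R̄²` with the standard small-sample series
  p-value.
* `kuiper_test()` — rotation-invariant circular analogue of
  Kolmogorov–Smirnov, with power against multimodal departures. The
  reported statistic is the Stephens-modified
  `V* = V·(√n + 0.155 + 0.24/√n)`, whose null distribution is stable in
  sample size, and the p-value is the asymptotic series
  `Σ 2(4k²V*² − 1)·e^{−2k²V*²}` truncated at 1e-10. The modified form is
  the one under which published critical bands (e.g. `V* = 1.834` at
  `n = 100` falling between the 5% and 2.5% points) are coherent, which
  is why it is the recorded statistic. Sample sizes below 5 are rejected
  rather than given an unreliable asymptotic p.
* `rose_bins()` — square-root-scaled orientation rose sectors (`√count`
  heights, so sector *area* is proportional to count). The sector width
  is a free parameter defaulting to 15° (24 sectors), a common
  rose-diagram resolution; squared heights always reconstruct the counts.

Both tests hold their nominal size under the uniform null in seeded
Monte-Carlo calibration (1,000 uniform samples of n = 100 in the test
suite; rejection rates at α = 0.05 fall within 0.05 ± 0.02).

## Synthetic surfaces

`generate_surface()` provides the fixtures every stage is exercised on:

* `tilted_plane` — a linear cost gradient; the walk direction is then
  analytically known, which is what the greedy-oracle tests rely on.
* `parabolic_valley` — a low-cost north–south trough with quadratic
  walls, the synthetic analogue of a river-corridor attractor between
  ridges. Walks released off-axis converge onto and then follow the axis
  (asserted in the suite as a mean off-axis distance below one lattice
  cell over the final steps).
* `random_field` — seeded white noise blurred with a separable Gaussian
  kernel (truncated at 3σ and renormalised), rescaled and clamped at
  zero: smooth, correlated, strictly reproducible per seed.

All three accept a NoData margin so boundary and masking paths are
routinely exercised. What these fixtures deliberately do **not** emulate:
real terrain anisotropy (uphill/downhill asymmetry is out of scope by
design), the long-range autocorrelation structure of actual DEM-derived
slope, and irregular NoData shapes such as coastlines. Tests passing on
these surfaces validate the mechanics and the statistics, not any claim
about a particular landscape.

## Problem sizes and runtime choices

The test suite runs on grids between 20×20 and 70×70 cells with walks of
12–60 steps (50–100 seeded walks per property), and the calibration
suites use 1,000 Monte-Carlo samples of n = 100 and 1,000 random lattice
walks — sizes chosen so the full suite completes in well under a minute
while every stochastic assertion still has narrow sampling error. The
acceptance script runs one 1000-step hexagonal walk on a 200×200 field,
the canonical per-walk length for this model family.

## File formats

Rasters are read and written as Esri ASCII grids (`.asc`, with an
optional `.prj` sidecar carrying the CRS string), values at full double
precision so write/read round trips are exact. Walks are exported as
GeoJSON FeatureCollections (points per visited cell centre; one
LineString per walk with its statistics as properties). Both are
plain-text formats readable by any mainstream GIS.

## Known limitations

* Cost is isotropic: the price of entering a cell does not depend on the
  direction of travel, so slope is a symmetric friction, not a hiking
  function.
* Single ring only: the decision catchment is one cell deep; larger
  catchments are expressed through `nsize`, not through multi-ring
  neighbourhoods.
* The density layer counts crossings of the centre polyline; it is a
  trace of realised routes, not a visitation-time or occupancy measure.
* One agent at a time: no interaction, memory beyond visited cells, or
  goal-seeking.
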