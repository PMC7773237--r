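---
title: "Modeling nomadic pastoralist movement on dynamic favorability surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nomadic pastoralist movement on dynamic favorability surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`pastoralsim` simulates nomadic pastoralist households moving across an
arid rangeland in monthly steps, driven by a single additive *favorability*
score per grid cell. The model has two entities: agents (one per household)
and a gridded physical environment whose layers change with the Somali
seasonal calendar — Jilaal (long dry, December–March), Gu (long rains,
April–June), Hagaa (short dry, July–September), Deyr (short rains,
October–November). December is attached to the Jilaal that spans the year
boundary.

Each environment layer is min–max normalized to [0, 1] and combined as

    score = v1 + v2 + v3 − 0.25·v4 − v5 − 0.25·v6

with pull layers v1 (vegetation, proxied by the soil-adjusted vegetation
index SAVI = (1+L)(NIR−Red)/(NIR+Red+L), L = 0.5), v2 (surface water,
present only in wet seasons — herders rely on wells and boreholes in the
dry months, so the layer is disabled then), v3 (artificial water points,
scored by normalized per-cell counts), and push layers v4 (terrain slope by
Horn's 3×3 method, degrees, normalized), v5 (conflict incidence), and v6
(proximity to ethnic-territory borders, weighted 1 / 0.5 / 0.25 for border
cells and 10 km / 20 km rings). Scores therefore lie in [−1.5, 3];
unsuitable cells (open water, bare soil) carry a `-Inf` sentinel and are
never selectable.

Conflict carries a one-season lag: the raw cell score for a season is the
event count of that season plus half the count of the preceding season.

### The monthly decision loop

At every tick each active agent:

1. draws a scouting radius uniformly between 15 and 30 km (expert-consensus
   monthly mobility of a household herd);
2. ranks all suitable cells whose centers fall inside the radius by score,
   breaking ties by distance (nearer first) and then row-major cell index,
   so the ordering is fully deterministic;
3. walks that list: its own cell means *stay*; a public cell is occupied
   immediately; a private cell requires a land-sharing deal, modeled as a
   Bernoulli draw with probability `pDeal`. Each failed deal increments a
   per-season counter; at the third failure in a season the agent leaves
   the pastoralist cycle permanently (IDP state) — the terminal drop-out.

On the first tick of each new season the current cell is excluded from the
candidate list, forcing relocation (modeling forage depletion); the agent
may return to that cell at later ticks. Private land is held by settlements:
cells within 14 km of a city or 4 km of a town centroid, radii chosen so
that roughly 80% of land remains public.

## Design choices where the design was open

Several aspects of the decision loop are underdetermined by the narrative
the model follows; the package fixes them as follows.

* **Deal probability.** Negotiation outcomes are a single Bernoulli
  parameter `pDeal` (default 0.5); nothing distinguishes landowners.
* **Three failures.** The drop-out counter accumulates across ticks and
  settlements within one season and resets at each season boundary.
* **Within-season re-evaluation.** An agent re-scores its neighbourhood
  every month; it stays only while its current cell remains the best
  candidate in that month's scouting disk.
* **Candidate exhaustion.** If every candidate is private and all deals
  fail while the counter is still below three, the agent stays put for the
  tick.
* **Staying costs no deal.** Reaching the current cell during the walk ends
  the tick as STAYED even on private land: a household already camped there
  holds its arrangement for the season.
* **Update order.** Agents are stepped in ascending id, but every
  (behavior seed, agent, tick) triple keys its own counter-based
  splitmix64 random stream, so results are independent of update order and
  of how many agents exist. Draw order within a tick is: one uniform for
  the radius, then one per private-cell deal attempt.
* **Normalization scope.** Per-layer min–max normalization is applied per
  season for water-point counts, but SAVI is normalized jointly across all
  seasons of a run and conflict is divided by the global maximum of the
  lag-weighted cell score over the whole window. Per-season normalization
  would rescale every season to the same [0, 1] range and erase exactly
  the wet/dry and drought signals (and the conflict lag semantics) the
  model exists to express. The conflict constant is logged in the run
  manifest.
* **Ethnic buffers in kilometers.** The border buffers are 10 km and 20 km
  (a 20 km gradient); meter-scale buffers would be invisible on a 1 km
  grid. Both distances are arguments.
* **Tie-breaks and edges.** Scouting disks are clipped at the grid
  boundary; slope uses edge replication; boundary points in district
  counting go to the first polygon in file order.

Seeds are split by role: `placementSeed` fixes start positions (identical
across runs), `behaviorSeed` drives movement; no unseeded randomness exists
anywhere in the pipeline.

## The synthetic landscape generator

`generateLandscape()` fabricates the *structure* of the study inputs, not
the marginals of any real dataset: districts and ethnic territories are
bounded Voronoi tessellations of spaced random seeds (contiguous,
non-overlapping, covering the grid); elevation and vegetation are
Gaussian-smoothed white noise (kernel width = correlation length — simpler
than spectral synthesis and adequate for testing); seasonal NIR/Red pairs
are constructed on the simplex NIR + Red = 1 so the implied SAVI equals the
target field exactly; conflict events are per-district per-season Poisson
counts scattered around a random within-district cluster center; water
points are clustered draws; surface water and bare soil are noise-field
threshold masks.

`somalilandPreset()` pins the generator to the study conditions: a 70 × 70
grid of 10 km cells (490,000 km², the study-area extent at reduced
resolution), seven districts named after the administrative regions of
Somaliland and Puntland with base populations fixed at ten times their
published 10%-sample agent counts (so `synthesizePopulation(pops, 0.10)`
yields exactly 22,575 agents), 132 monthly ticks from January 2008,
drought-year vegetation depression in simulation years 3–4 and 9 (echoing
the 2010–12 and 2016–17 droughts), a 20% private-land share (the preset
adds seeded towns until the expert-elicited 80/20 public/private split is
reached), and per-district conflict intensities chosen once to echo the
reported hierarchy (Bari by far the most conflict-affected, Nugaal the
least). Wet-season SAVI uplift defaults to +0.2 applied to the base field
before drought scaling, so the configured uplift is preserved exactly in
expectation.

What the generator deliberately does not emulate: real spatial
autocorrelation structure beyond a single correlation length, coastlines
and true district geometries, population gradients within districts, and
any coupling between conflict and vegetation. Tests passing on synthetic
landscapes therefore validate the *mechanics* of the model and analyses,
not any claim about real Somali migration.

## Spatial analysis

* **Counts and changes.** Active agents are tallied per district (points
  outside every district are excluded but reported); change tables are
  end-minus-start differences; `rangeSpan()` reports the most and least
  populated districts and their gap.
* **Jenks natural breaks.** The exact Fisher dynamic program minimizing
  within-class sums of squared deviations, verified against exhaustive
  search for small inputs.
* **Kernel density.** The quadratic (Epanechnikov-family) kernel
  `density(c) = (1/r²) Σ (3/π)·popᵢ·(1 − (dᵢ/r)²)²` over points within the
  search radius, evaluated at cell centers and reported per km². The 3/π
  constant makes the surface integrate to the total population (verified by
  quadrature to 0.5%). Map statistics use the population (1/N) standard
  deviation.
* **Standard deviational ellipses.** Centroid and covariance with the 1/n
  divisor; semi-axes are `nSd`·√eigenvalues (default 2 SD); rotation is
  the major-axis bearing clockwise from north in [0, 180). At 2 SD an
  isotropic normal cloud is covered at about 1 − e⁻² ≈ 86.5% (the Rayleigh
  closed form); the package does not force any higher containment figure.

## Numerical and degenerate-input conventions

Nodata (`NA`) propagates through layer algebra and is ignored by
normalization statistics; a constant layer normalizes to zeros with a
warning; an all-nodata layer is an error. Layer operations require exact
grid alignment (origin, cell size, shape). Distances are planar Euclidean
meters throughout (the package assumes a projected, UTM-like CRS); cells
are identified by (row, column) with row 1 northernmost, and agents sit on
cell centers. Collinear point sets yield a degenerate (zero-area) ellipse
with a warning. An empty scouting disk leaves the agent in place with a
logged count.

## Problem sizes used in the test suite

The bundled checks run the preset landscape (22,575 agents, 132 ticks,
three behavior-seed replicates plus one 25% run of 56,442 agents) and a
40 × 40 × 5 km invariants landscape with 2,000 agents over 132 ticks —
sizes chosen so the whole suite completes in about a minute on one core
while still exercising every seasonal transition of an 11-year run. The
engine's tick loop is implemented in C++ (Rcpp); the exported R step
(`stepAgent()`) consumes the identical random streams and is tested for
draw-for-draw agreement with the engine, which is what makes the
hand-traced oracle and the fast path mutually checking implementations.

## Worked example

```{r example}
library(pastoralsim)

ls  <- generateLandscape(somalilandPreset(seed = 1))
env <- buildSeasonStacks(ls)
agents <- placeAgents(synthesizePopulation(ls@basePopulations, 0.10),
                      ls@districtMatrix, ls@privateMask,
                      ls@suitabilityMask, placementSeed = 11)
cfg <- simulationConfig(placementSeed = 11, behaviorSeed = 101)
sim <- runSimulation(env$stacks, agents, cfg,
                     recordTicks = defaultCheckpoints(132))
sim

ct <- agentDistrictCounts(trajectory(sim), 130, ls@districtMatrix)
rangeSpan(ct$counts)
```

## Known limitations

Agents do not interact: there is no herd-size dynamics, resource
competition, livestock economics or disease, and no re-entry of dropped-out
households. The favorability score is unweighted beyond its fixed signed
coefficients (though the six weights are configurable), and deal success is
homogeneous across settlements. Reprojection and resampling are out of
scope — inputs must already be on the model grid — and no cartographic
rendering is provided.
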