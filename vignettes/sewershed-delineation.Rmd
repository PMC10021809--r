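---
title: "Delineating sewersheds and estimating the populations they serve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating sewersheds and estimating the populations they serve}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sewersheds)
```

## The problem

Wastewater-based epidemiology infers community health signals — viral
load, drug metabolites — from samples taken at wastewater treatment
plants. Every such measurement needs a population denominator: how many
people drain to this plant? That requires a *sewershed*, the polygon of
land whose sewers all flow to one collection point, and an estimate of the
population living inside it. Where no authoritative sewershed maps exist,
boundaries must be assembled from indirect evidence: tax parcels flagged
as connected to public sewer, manhole and sewer-main layers, sewer-district
billing tables, village boundaries, and maps or shapefiles provided by
plant operators.

This package implements that assembly line as reusable, tested components:

1. **build** — construct sewershed polygons from parcels, infrastructure,
   districts and provided boundaries;
2. **estimate** — apportion census populations into each sewershed by
   overlap area and project them forward with a growth rate;
3. **qa** — validate the boundaries by correlating each plant's permitted
   discharge capacity with the population, density and area it was
   assigned;
4. **simulate** — generate synthetic counties with known ground truth so
   that 1–3 can be exercised and tested end to end without any external
   data.

## The estimation model

### Area-weighted apportionment

Census units (blocks, and block groups at two vintages) are overlaid on
the sewershed polygon. Each unit $u$ with population $P_u$ contributes

$$ w_u = \frac{|S \cap u|}{|u|}, \qquad \hat P(S) = \sum_u w_u P_u, $$

assuming population is uniformly distributed within a unit. The uniform
assumption is taken literally; no dasymetric refinement is attempted.
Blocks are used for the base 2010 figure because they are the smallest
published geography; block groups, available at both the 2010 decennial
and a 2018 survey vintage, supply the trend.

### Growth rate and projection

With block-group apportionments $P_{2010}$ and $P_{2018}$, the annual
rate of change is linear over the eight-year window,

$$ g = \frac{(P_{2018} - P_{2010}) / P_{2010}}{8}, $$

and the 2020 estimate compounds the block-based 2010 figure over ten
years,

$$ P_{2020} = P_{2010}^{\text{(block)}} \, (1 + g)^{10}. $$

A zero 2010 base yields rate 0 with a `zero_base` flag rather than an
error (the ratio is undefined but the pipeline should stay total); a rate
at or below $-1/8$ is flagged `collapse`; projection with $g \le -1$ is a
domain error.

### Validation by discharge capacity

A plant's permitted discharge capacity scales with the population it
serves, so the Pearson correlation between $\log_{10}$ capacity and
$\log_{10}$ population (and density, and area) over all plants — overall
and stratified by construction method — is a sanity check on the
boundaries. Both variables are right-skewed, hence the log transform;
raw-scale correlations are reported alongside. Non-positive values are
excluded explicitly, never coerced. Strata with fewer than three usable
records, or zero variance (e.g. the constant density of a noise-free
scene), are reported as not estimable without suppressing other strata.
P-values come from the $t$ statistic on $n-2$ degrees of freedom and are
reported at full precision without multiple-testing correction.

## Construction workflows

For each plant the builder applies the best available method, in priority
order:

| method | input | rule |
|---|---|---|
| `provided` | operator/municipal boundary | used verbatim, never modified |
| `danc_merge` | regional-authority boundary | unioned with public parcels intersecting it or within `cluster_gap` |
| `address_list` | billing addresses | normalized exact match against parcel addresses, then dissolve |
| `infrastructure` | manholes, mains | parcels within `manhole_radius` of a manhole or `main_buffer` of a main |
| `physical_map` | georeferenced boundary | parcels whose interior point falls inside, then dissolve |
| `parcel_district` | district table | parcels grouped by district label, routed to plants |
| `parcel_cluster` | public-sewer flags | distance clustering, nearest-plant assignment |
| `village_fallback` | village polygon | used verbatim as a flagged placeholder |

Parcels claimed by an earlier workflow are withdrawn from the pool, so
every public-sewer parcel ends up in at most one sewershed, and — on a
scene with complete data — exactly one.

Distance thresholds (`main_buffer` 30, `manhole_radius` 30, `cluster_gap`
50 length units) are exposed configuration, not derived quantities: the
source procedures speak only of "adjacent" and "proximate" parcels. All
thresholds are closed (a parcel exactly at the limit is selected).
Cluster-to-plant ties break by lowest plant id, and a cluster containing a
plant's point belongs to that plant regardless of distance. Parcel-in-
boundary membership uses the representative-interior-point rule by
default because it is cheap and deterministic; an area-majority rule is
available as a config switch (`membership = "area_majority"`), and the two
agree on all parcels whose overlap is not close to one half.

## Geometry engine

No polygon-geometry library is assumed: the package carries its own exact
planar engine. All coordinates live in one abstract Cartesian plane
(units read as meters); there is no geodesy, matching the practice of
computing areas on projected state-plane data. Polygons are simple rings;
multipart regions hold interior-disjoint parts. The primitives are:

* areas by the shoelace formula;
* intersection areas by decomposing both operands into convex pieces
  (ear-clipping triangulation for non-convex rings) and summing
  convex–convex clip areas (Sutherland–Hodgman);
* union measure by recursive inclusion–exclusion over convex pieces,
  exact for arbitrary overlaps;
* distances from segment–segment and point–segment kernels;
* Voronoi cells by half-plane clipping of the bounding rectangle.

A *dissolve* is represented as the multipart region of its member parcels
rather than a recomputed outer boundary polyline: every observable
downstream quantity — union area, overlap weights, containment, component
counts, distances — is computed exactly from that representation, and the
shared parcel edges are measure-zero. The `gap_fill` parameter performs
topological closing: parts within twice the fill distance are merged into
one component, as an outward-then-inward buffer would, without inflating
the area. Sliver intersections below $10^{-9}$ of a census unit's area
are treated as numerical noise and dropped.

## The synthetic-scene generator

`generateScene()` produces a self-consistent county with known truth:

* a rectangular region tiled by an $n_x \times n_y$ grid of census
  blocks, nested exactly into block groups of consecutive runs — group
  geometry *is* the union of its member blocks, so nesting is exact by
  construction;
* treatment plants placed on a jittered coarse grid (so pairwise
  separations stay large) with base-10 log-normal permitted capacities;
* ground-truth sewersheds as Voronoi cells of the plant sites clipped to
  the region and shrunk inward by one parcel size, which makes
  inter-sewershed gaps at least twice the parcel size — larger than any
  default clustering threshold, so recovery is unambiguous;
* parcels tiling each sewershed at `parcel_size`, a configurable fraction
  flagged `public`, with district labels, addresses and municipality ids;
  coarser unsewered filler parcels in the countryside;
* populations tied to capacity through
  $\log_{10} P = a + b \log_{10} C + \varepsilon$,
  $\varepsilon \sim N(0, \sigma)$, spread equally over the blocks that
  lie fully inside the sewershed and whose block group does not straddle
  two sewersheds; all other blocks carry population zero;
* per-sewershed annual growth rates $g$ applied *linearly* to 2018 block
  groups, $P_{2018} = P_{2010}(1 + 8g)$ — the exact inverse of the
  estimator's rate formula, so rate recovery isolates estimator
  correctness from model mismatch.

Random streams are split per layer (placement, capacities, population
noise, growth rates, parcel flags), so changing one configuration field
perturbs only its own layer.

### Default conditions

The defaults describe a small county: a 3000 × 3000 m region, 15 × 15
blocks of 200 m, block groups of 3 blocks, five plants,
$\log_{10} C \sim N(-0.3, 0.8)$ (median capacity about 0.5 mgd, matching
the small municipal plants that dominate such inventories), $a = 4$,
$b = 1$ (1 mgd ↔ about 10,000 people, the common design rule of ~100
gallons per person-day), $\sigma = 0.12$, growth rates uniform in
$[-0.005, 0.02]$ per year, 60 m parcels with 90% of in-sewershed parcels
flagged public, and an urban county threshold of 400 persons/km² of
sewered density. Parcel sizes and counts are free choices — nothing in
the underlying procedure constrains them — picked so that a scene holds
a few thousand parcels and the full pipeline runs in seconds.

### What the generator does and does not emulate

It reproduces the *statistical* structure the analysis relies on: nested
geographies with consistent counts, log-normal capacities, a log-linear
population–capacity law, sewered/unsewered parcel flags, district labels,
and ground truth for every derived quantity. It does **not** emulate
street networks, hydrology, force mains, combined-sewer runoff areas,
irregular parcel shapes, census suppression of small counts, or seasonal
population change. Passing tests therefore demonstrate correctness of
the *computations* — overlays, clustering, rates, correlations — not
robustness to every pathology of real cadastral data.

Two deliberate idealizations matter when interpreting test results.
First, populated blocks lie strictly inside their sewershed, so
block-level apportionment against the true boundary is exact; real
blocks straddle boundaries and apportionment error there is governed by
the uniform-density assumption. Second, sewershed areas are Voronoi
cells, not constructed proportional to population, so the area–capacity
correlation on a geometric scene is weaker than the population–capacity
one; the noise-free limit in which all three log correlations equal 1 is
exercised on directly constructed QA records with area proportional to
population at fixed density.

## Numerical choices

* Geometry tolerances: degenerate clip outputs below $10^{-12}$ area
  units are discarded; ring orientation is normalized counter-clockwise
  on ingest (geometry repair), and duplicated closing vertices dropped.
* Apportionment weights are capped at 1 and slivers below $10^{-9}$ of
  unit area dropped.
* Fractional persons are retained end to end; rounding is an explicit
  output option (`round_outputs`).
* Determinism: all layer order is by id; assignment ties break by lowest
  plant id; two runs of the pipeline with one seed write byte-identical
  CSV outputs.
* Overlapping sewersheds (multi-influent plants) are permitted; the
  apportionment reports each sewershed independently and any
  double-counting is visible in the mass-conservation check rather than
  silently resolved.

## Problem sizes

The test-suite and acceptance scenes use 10 × 10 to 15 × 15 block grids
with three to five plants (roughly 1000–2200 parcels), 50
sewershed/block pairs with $10^5$-point Monte-Carlo area checks, and 20
replicate capacity–population draws at $n = 100$ plants. These sizes
were chosen so each property is measured with comfortable statistical
margin while a full run stays in the tens of seconds on one CPU.

## Known limitations

* The engine supports polygons without holes; a sewershed surrounding an
  unsewered island is represented by its parts, not an explicit hole.
* Address matching is exact-after-normalization; no fuzzy matching.
* The eight-year divisor in the growth rate treats the 2018 survey
  vintage literally; no adjustment for the survey's five-year window.
* Counties in the generator are vertical strips — adequate for testing
  urban/rural summaries, not a model of real county shapes.
* No reprojection: all layers must already share one planar system, and
  the pipeline refuses mixed systems rather than guessing.
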