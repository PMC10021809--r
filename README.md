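# sewersheds

Delineate wastewater treatment plant service areas ("sewersheds"),
estimate the population each one serves, and validate the boundaries —
the upstream denominator work that wastewater-based epidemiology depends
on.

Wastewater surveillance measures pathogens and substances at a treatment
plant, but interpreting a sample requires knowing the population that
drains to it. Where no authoritative service-area maps exist, boundaries
must be assembled from indirect evidence: tax parcels flagged as
connected to public sewer, manhole/sewer-main layers, sewer-district
billing tables, boundaries provided by operators, and village polygons
as a last resort. This package implements that assembly line, the census
population model on top of it, and a synthetic-geography generator with
known ground truth so everything runs and is tested without external
data.

## The model

**Apportionment.** Census units are overlaid on a sewershed `S`; each
unit `u` with population `P_u` contributes weight
`w_u = |S ∩ u| / |u|` (uniform density within units), and
`P̂(S) = Σ w_u P_u`.

**Growth.** From block-group apportionments at two vintages,

    g = ((P_2018 − P_2010) / P_2010) / 8        (per year)
    P_2020 = P_2010_block × (1 + g)^10

**Validation.** Permitted discharge capacity scales with population
served, so Pearson correlations of `log10(capacity)` against
`log10(population)`, `log10(density)` and `log10(area)` — overall and
per construction method — flag suspect boundaries.

All geometry is planar Cartesian (units read as meters). The package
carries its own exact polygon engine (triangulation + convex clipping
for intersection areas, recursive inclusion–exclusion for union
measures, Voronoi by half-plane clipping), and reads/writes GeoJSON,
ESRI Shapefile and CSV.

## Worked example

```r
library(sewersheds)

scene <- generateScene(sceneConfig(seed = 42))
scene
#> SewerScene
#>   region: 3000 x 3000 | blocks: 225 | block groups: 75 | parcels: 2150
#>   plants: 5 | true sewersheds: 5 | counties: 2

sheds <- buildSewersheds(sceneParcels(scene), scenePlants(scene), builderConfig())
est <- estimateAll(sheds, sceneCensus(scene, "blocks2010"),
                   sceneCensus(scene, "bg2010"), sceneCensus(scene, "bg2018"))
est[, c("shed_id", "plant_id", "method", "pop10_blk", "rate", "pop2020")]
#>   shed_id plant_id         method pop10_blk      rate pop2020
#> 1  SH_P01      P01 parcel_cluster     21722  0.015842   25419
#> 2  SH_P02      P02 parcel_cluster     11977  0.008299   13009
#> 3  SH_P03      P03 parcel_cluster      2932  0.012712    3327
#> 4  SH_P04      P04 parcel_cluster      1239 -0.003081    1201
#> 5  SH_P05      P05 parcel_cluster      8488  0.005673    8982

rep <- qaReport(qaRecords(est, scenePlants(scene)))
rep[rep$stratum == "overall" & rep$scale == "log10", ]
#>  stratum scale                pair n      r       p estimable
#>  overall log10     capacity_vs_pop 5 0.9589 0.00993      TRUE
#>  overall log10 capacity_vs_density 5 0.7882 0.11319      TRUE
#>  overall log10    capacity_vs_area 5 0.5224 0.36647      TRUE
```

Each sewershed here was built by distance-clustering the public-sewer
parcels and assigning clusters to the nearest plant (`parcel_cluster`,
the lowest rung of the method hierarchy; operator-provided boundaries,
address lists, infrastructure layers and district tables take precedence
when supplied). `pop10_blk` is the block-apportioned 2010 population,
`rate` the annual growth from block-group vintages, `pop2020` the
ten-year projection. The generator's planted populations for this seed
are 23723, 13407, 3282, 1341 and 9493 — the estimates land close, with
the shortfall coming from the ~10% of in-sewershed parcels not flagged
public. The high log-scale capacity–population correlation (r = 0.96) is
the boundary sanity check.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/sewershed.R run --config pipeline.yaml --seed 7 --out out/
```

with subcommands `simulate | build | estimate | qa | run` and distinct
exit codes for schema, geometry, configuration, I/O and reference
errors.

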