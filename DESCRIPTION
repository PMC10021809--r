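Package: sewersheds
Title: Sewershed Delineation, Census Population Apportionment and
    Capacity-Based Validation for Wastewater-Based Epidemiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constructing wastewater treatment plant service
    areas ("sewersheds") from tax parcels, sewer infrastructure, district
    tables and provided boundaries; estimating the population each
    sewershed serves by area-weighted apportionment of census blocks and
    block groups with a linear growth-rate projection; and validating
    the resulting boundaries through log10-scale Pearson correlation of
    permitted discharge capacity against population, density and area,
    overall and stratified by construction method.  A synthetic-geography
    generator produces self-consistent counties (nested census units,
    sewered parcels, plants with log-normal capacities, ground-truth
    sewersheds) so the whole pipeline runs and is testable without any
    external data.  All geometry is planar Cartesian; a built-in exact
    polygon engine (triangulation plus convex clipping) provides areas,
    overlays and distances.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    foreign
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
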