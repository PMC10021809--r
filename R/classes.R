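# S4 containers for the pipeline's layers.
#
# Each layer couples an attribute data.frame with a parallel list of
# geometries (gpoly for areal layers, xy coordinates for plants).  Column
# names are kept to <= 10 characters throughout so attribute tables survive
# dBase (.dbf) round trips unchanged.

#' @import methods
NULL

setClassUnion("dfOrNull", c("data.frame", "NULL"))

#' Tax-parcel layer
#'
#' Cadastral lots with a public-sewer flag and optional district, address
#' and municipality attributes.  `data` columns: `parcel_id` (unique),
#' `sewer_flag` (one of `"public"`, `"private"`, `"unknown"`), `district`
#' (NA allowed), `address` (NA allowed), `muni_id` (NA allowed).
#'
#' @slot data data.frame of parcel attributes.
#' @slot geometry list of `gpoly`, one per row.
#' @export
setClass("ParcelSet", representation(data = "data.frame", geometry = "list"))

#' Census-unit layer
#'
#' Polygons with population counts at a stated vintage and level.  `data`
#' columns: `unit_id` (unique), `pop` (non-negative), `vintage`
#' (`"dec2010"` or `"acs2018"`), `level` (`"block"` or `"block_group"`).
#'
#' @slot data data.frame of unit attributes.
#' @slot geometry list of `gpoly`, one per row.
#' @export
setClass("CensusLayer", representation(data = "data.frame", geometry = "list"))

#' Treatment-plant layer
#'
#' Point facilities with permitted discharge capacity (millions of gallons
#' per day in reporting).  `data` columns: `plant_id` (unique), `name`,
#' `capacity` (> 0), `avg_flow` (NA allowed), `county_id`, `x`, `y`.
#'
#' @slot data data.frame of plant attributes including coordinates.
#' @export
setClass("PlantSet", representation(data = "data.frame"))

#' Sewershed layer
#'
#' Constructed service-area polygons, one row per sewershed.  `data`
#' columns: `shed_id` (unique), `plant_id`, `method` (construction method),
#' `area`; slot `members` holds each sewershed's member parcel ids.
#'
#' @slot data data.frame of sewershed attributes.
#' @slot geometry list of `gpoly`.
#' @slot members list of character vectors of parcel ids (may be empty for
#'   provided boundaries).
#' @export
setClass("SewershedSet",
         representation(data = "data.frame", geometry = "list",
                        members = "list"))

#' Synthetic scene bundle
#'
#' A self-consistent synthetic county: nested census geography at two
#' vintages, parcels, plants, ground-truth sewersheds, and the generating
#' truth (per-plant populations and annual growth rates).
#'
#' @slot blocks2010 `CensusLayer` of 2010 blocks.
#' @slot blockGroups2010 `CensusLayer` of 2010 block groups.
#' @slot blockGroups2018 `CensusLayer` of 2018 block groups.
#' @slot parcels `ParcelSet`.
#' @slot plants `PlantSet`.
#' @slot trueSewersheds `SewershedSet` of ground-truth service areas.
#' @slot trueGrowthRates named numeric, per-year fraction per plant id.
#' @slot truePopulations named numeric, persons per plant id.
#' @slot counties data.frame with `county_id`, `urban` flag and total
#'   county population.
#' @slot config the `SceneConfig` list used to generate the scene.
#' @export
setClass("SewerScene",
         representation(blocks2010 = "CensusLayer",
                        blockGroups2010 = "CensusLayer",
                        blockGroups2018 = "CensusLayer",
                        parcels = "ParcelSet",
                        plants = "PlantSet",
                        trueSewersheds = "SewershedSet",
                        trueGrowthRates = "numeric",
                        truePopulations = "numeric",
                        counties = "data.frame",
                        config = "list"))

.checkGeomLayer <- function(object, idcol) {
  msg <- character(0L)
  d <- object@data
  if (!idcol %in% names(d)) msg <- c(msg, sprintf("missing column '%s'", idcol))
  else if (anyDuplicated(d[[idcol]])) msg <- c(msg, sprintf("'%s' not unique", idcol))
  if (nrow(d) != length(object@geometry))
    msg <- c(msg, "geometry list length must equal nrow(data)")
  if (length(object@geometry) &&
      !all(vapply(object@geometry, is.gpoly, TRUE)))
    msg <- c(msg, "all geometries must be gpoly objects")
  msg
}

setValidity("ParcelSet", function(object) {
  msg <- .checkGeomLayer(object, "parcel_id")
  d <- object@data
  if ("sewer_flag" %in% names(d)) {
    if (!all(d$sewer_flag %in% c("public", "private", "unknown")))
      msg <- c(msg, "sewer_flag must be public/private/unknown")
  } else msg <- c(msg, "missing column 'sewer_flag'")
  if (length(object@geometry)) {
    a <- vapply(object@geometry, gpArea, 0)
    if (any(a <= 0)) msg <- c(msg, "all parcels must have positive area")
  }
  if (length(msg)) msg else TRUE
})

setValidity("CensusLayer", function(object) {
  msg <- .checkGeomLayer(object, "unit_id")
  d <- object@data
  if (!"pop" %in% names(d)) msg <- c(msg, "missing column 'pop'")
  else if (any(d$pop < 0)) msg <- c(msg, "populations must be non-negative")
  if ("vintage" %in% names(d) && !all(d$vintage %in% c("dec2010", "acs2018")))
    msg <- c(msg, "vintage must be dec2010/acs2018")
  if ("level" %in% names(d) && !all(d$level %in% c("block", "block_group")))
    msg <- c(msg, "level must be block/block_group")
  if (length(msg)) msg else TRUE
})

setValidity("PlantSet", function(object) {
  msg <- character(0L)
  d <- object@data
  need <- c("plant_id", "capacity", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) msg <- c(msg, paste("missing column(s):", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(d$plant_id)) msg <- c(msg, "'plant_id' not unique")
    if (any(d$capacity <= 0)) msg <- c(msg, "discharge capacity must be > 0")
  }
  if (length(msg)) msg else TRUE
})

setValidity("SewershedSet", function(object) {
  msg <- .checkGeomLayer(object, "shed_id")
  d <- object@data
  need <- c("plant_id", "method", "area")
  miss <- setdiff(need, names(d))
  if (length(miss)) msg <- c(msg, paste("missing column(s):", paste(miss, collapse = ", ")))
  if (length(object@members) != nrow(d))
    msg <- c(msg, "members list length must equal nrow(data)")
  if ("area" %in% names(d) && length(object@geometry)) {
    a <- vapply(object@geometry, gpArea, 0)
    bad <- abs(d$area - a) > 1e-9 * pmax(a, 1)
    if (any(bad)) msg <- c(msg, "stored area disagrees with computed geometry area")
  }
  if (length(msg)) msg else TRUE
})

.METHODS <- c("provided", "address_list", "infrastructure", "physical_map",
              "danc_merge", "parcel_district", "parcel_cluster",
              "village_fallback")

#' Sewershed construction methods, in priority order
#' @return character vector of method labels.
#' @export
sewershedMethods <- function() .METHODS

## ---- constructors ----------------------------------------------------------

#' Construct a ParcelSet
#' @param parcel_id character ids (unique).
#' @param geometry list of `gpoly`.
#' @param sewer_flag character, `public`/`private`/`unknown`.
#' @param district,address,muni_id optional character attributes.
#' @return a `ParcelSet`.
#' @export
ParcelSet <- function(parcel_id, geometry,
                      sewer_flag = rep("unknown", length(parcel_id)),
                      district = rep(NA_character_, length(parcel_id)),
                      address = rep(NA_character_, length(parcel_id)),
                      muni_id = rep(NA_character_, length(parcel_id))) {
  new("ParcelSet",
      data = data.frame(parcel_id = as.character(parcel_id),
                        sewer_flag = as.character(sewer_flag),
                        district = as.character(district),
                        address = as.character(address),
                        muni_id = as.character(muni_id),
                        stringsAsFactors = FALSE),
      geometry = geometry)
}

#' Construct a CensusLayer
#' @param unit_id character ids (unique).
#' @param geometry list of `gpoly`.
#' @param pop non-negative populations (fractional persons allowed).
#' @param vintage `"dec2010"` or `"acs2018"`.
#' @param level `"block"` or `"block_group"`.
#' @return a `CensusLayer`.
#' @export
CensusLayer <- function(unit_id, geometry, pop, vintage, level) {
  new("CensusLayer",
      data = data.frame(unit_id = as.character(unit_id),
                        pop = as.numeric(pop),
                        vintage = rep_len(vintage, length(unit_id)),
                        level = rep_len(level, length(unit_id)),
                        stringsAsFactors = FALSE),
      geometry = geometry)
}

#' Construct a PlantSet
#' @param plant_id character ids (unique).
#' @param x,y planar coordinates.
#' @param capacity permitted discharge capacity (> 0), volume/day.
#' @param name facility names.
#' @param avg_flow optional average daily flow.
#' @param county_id optional county identifier.
#' @return a `PlantSet`.
#' @export
PlantSet <- function(plant_id, x, y, capacity,
                     name = paste("WWTP", plant_id),
                     avg_flow = rep(NA_real_, length(plant_id)),
                     county_id = rep(NA_character_, length(plant_id))) {
  new("PlantSet",
      data = data.frame(plant_id = as.character(plant_id),
                        name = as.character(name),
                        capacity = as.numeric(capacity),
                        avg_flow = as.numeric(avg_flow),
                        county_id = as.character(county_id),
                        x = as.numeric(x), y = as.numeric(y),
                        stringsAsFactors = FALSE))
}

#' Construct a SewershedSet
#' @param shed_id character ids (unique).
#' @param plant_id owning plant per sewershed.
#' @param geometry list of `gpoly`.
#' @param method construction method label per sewershed.
#' @param members list of character vectors of member parcel ids.
#' @return a `SewershedSet`.
#' @export
SewershedSet <- function(shed_id, plant_id, geometry, method,
                         members = rep(list(character(0L)), length(shed_id))) {
  stopifnot(all(method %in% .METHODS))
  new("SewershedSet",
      data = data.frame(shed_id = as.character(shed_id),
                        plant_id = as.character(plant_id),
                        method = as.character(method),
                        area = vapply(geometry, gpArea, 0),
                        stringsAsFactors = FALSE),
      geometry = geometry, members = members)
}

## ---- generics and accessors ------------------------------------------------

#' Number of features in a layer
#' @param x a layer object.
#' @return integer count.
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' Attribute table of a layer
#' @param x a layer object.
#' @return data.frame.
#' @export
setGeneric("featureData", function(x) standardGeneric("featureData"))

#' Geometry list of a layer
#' @param x a layer object.
#' @return list of `gpoly` (points for `PlantSet`).
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' Subset a layer by feature index or id
#' @param x a layer object.
#' @param i integer or logical index.
#' @return a layer of the same class.
#' @export
setGeneric("subsetFeatures", function(x, i) standardGeneric("subsetFeatures"))

for (cl in c("ParcelSet", "CensusLayer", "SewershedSet")) {
  setMethod("nFeatures", cl, function(x) nrow(x@data))
  setMethod("featureData", cl, function(x) x@data)
  setMethod("geometry", cl, function(x) x@geometry)
}
setMethod("nFeatures", "PlantSet", function(x) nrow(x@data))
setMethod("featureData", "PlantSet", function(x) x@data)
setMethod("geometry", "PlantSet", function(x)
  lapply(seq_len(nrow(x@data)), function(i) c(x@data$x[i], x@data$y[i])))

setMethod("subsetFeatures", "ParcelSet", function(x, i)
  new("ParcelSet", data = x@data[i, , drop = FALSE], geometry = x@geometry[i]))
setMethod("subsetFeatures", "CensusLayer", function(x, i)
  new("CensusLayer", data = x@data[i, , drop = FALSE], geometry = x@geometry[i]))
setMethod("subsetFeatures", "PlantSet", function(x, i)
  new("PlantSet", data = x@data[i, , drop = FALSE]))
setMethod("subsetFeatures", "SewershedSet", function(x, i)
  new("SewershedSet", data = x@data[i, , drop = FALSE],
      geometry = x@geometry[i], members = x@members[i]))

.showLayer <- function(object, what) {
  cat(sprintf("%s with %d feature(s)\n", what, nrow(object@data)))
  if (nrow(object@data)) {
    print(utils::head(object@data, 4L))
    if (nrow(object@data) > 4L) cat("...\n")
  }
  invisible(object)
}

setMethod("show", "ParcelSet", function(object) {
  .showLayer(object, "ParcelSet")
  tb <- table(object@data$sewer_flag)
  cat("sewer flags:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
})
setMethod("show", "CensusLayer", function(object) {
  .showLayer(object, sprintf("CensusLayer [%s/%s]",
                             object@data$vintage[1L], object@data$level[1L]))
  cat(sprintf("total population: %.2f\n", sum(object@data$pop)))
})
setMethod("show", "PlantSet", function(object)
  .showLayer(object, "PlantSet (discharge capacity in volume/day)"))
setMethod("show", "SewershedSet", function(object) {
  .showLayer(object, "SewershedSet")
  cat("methods:", paste(sort(unique(object@data$method)), collapse = ", "), "\n")
})
setMethod("show", "SewerScene", function(object) {
  cat("SewerScene\n")
  cat(sprintf("  region: %g x %g | blocks: %d | block groups: %d | parcels: %d\n",
              object@config$region_width, object@config$region_height,
              nFeatures(object@blocks2010), nFeatures(object@blockGroups2010),
              nFeatures(object@parcels)))
  cat(sprintf("  plants: %d | true sewersheds: %d | counties: %d\n",
              nFeatures(object@plants), nFeatures(object@trueSewersheds),
              nrow(object@counties)))
  invisible(object)
})

#' @describeIn SewerScene-class parcels accessor
#' @param scene a `SewerScene`.
#' @export
sceneParcels <- function(scene) scene@parcels
#' @describeIn SewerScene-class plants accessor
#' @param scene a `SewerScene`.
#' @export
scenePlants <- function(scene) scene@plants
#' @describeIn SewerScene-class ground-truth sewersheds accessor
#' @param scene a `SewerScene`.
#' @export
sceneTrueSewersheds <- function(scene) scene@trueSewersheds
#' @describeIn SewerScene-class census layer accessor
#' @param scene a `SewerScene`.
#' @param which one of `"blocks2010"`, `"bg2010"`, `"bg2018"`.
#' @export
sceneCensus <- function(scene, which = c("blocks2010", "bg2010", "bg2018")) {
  switch(match.arg(which),
         blocks2010 = scene@blocks2010,
         bg2010 = scene@blockGroups2010,
         bg2018 = scene@blockGroups2018)
}
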