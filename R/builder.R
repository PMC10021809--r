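# Sewershed construction.
#
# Implements the computational parts of the digitization workflows used to
# assemble service areas: pass-through of provided boundaries, address-list
# matching against parcels, proximity selection against manholes and sewer
# mains, parcel selection within a supplied (physical-map) boundary,
# district grouping, provided-boundary augmentation with adjacent public
# parcels, distance clustering with nearest-plant assignment, and a
# village-boundary placeholder of last resort.  Parcel-derived geometries
# are dissolved into a single multipart region per sewershed.

#' Builder configuration
#'
#' Distance thresholds (length units) for the construction workflows.  None
#' of these is dictated by the underlying procedure, which speaks only of
#' "adjacent" and "proximate" features; they are deliberate, exposed
#' defaults.
#'
#' @param main_buffer buffer distance around sewer mains (default 30).
#' @param manhole_radius selection radius around manholes (default 30).
#' @param cluster_gap maximum boundary-to-boundary gap linking parcels into
#'   one system, and the adjacency distance for boundary augmentation
#'   (default 50).
#' @param dissolve_gap_fill closing distance applied when dissolving
#'   (components within `2 * dissolve_gap_fill` are merged; default 0).
#' @param membership parcel-in-boundary rule: `"interior_point"` (default)
#'   or `"area_majority"`.
#' @return a named list of class `BuilderConfig`.
#' @export
builderConfig <- function(main_buffer = 30, manhole_radius = 30,
                          cluster_gap = 50, dissolve_gap_fill = 0,
                          membership = c("interior_point", "area_majority")) {
  if (any(c(main_buffer, manhole_radius, cluster_gap, dissolve_gap_fill) < 0))
    configError("all builder distances must be non-negative")
  structure(list(main_buffer = main_buffer, manhole_radius = manhole_radius,
                 cluster_gap = cluster_gap,
                 dissolve_gap_fill = dissolve_gap_fill,
                 membership = match.arg(membership),
                 tie_break = "lowest_plant_id"),
            class = c("BuilderConfig", "list"))
}

.checkBoundary <- function(boundary) {
  if (!is.gpoly(boundary)) geometryError("boundary must be a gpoly")
  if (gpArea(boundary) <= 0) geometryError("boundary has no area")
  invisible(boundary)
}

#' Dissolve parcels into one service-area region
#'
#' Returns the union of the parcel polygons as a multipart region whose
#' parts are the (interior-disjoint) parcels; connected components under
#' the closing distance `2 * gap_fill` are recorded in the result's
#' `components` attribute, so `gap_fill > 0` bridges gaps up to twice its
#' value exactly as an outward-then-inward buffer would, without inflating
#' the area.
#'
#' @param parcels a `ParcelSet` (non-empty).
#' @param gap_fill non-negative closing distance.
#' @return a `gpoly` with attributes `components` (integer label per part)
#'   and `parcel_id` (id per part).
#' @export
dissolveParcels <- function(parcels, gap_fill = 0) {
  if (nFeatures(parcels) == 0L)
    emptyInputError("dissolveParcels: no parcels to dissolve")
  if (gap_fill < 0) configError("gap_fill must be non-negative")
  geoms <- geometry(parcels)
  ids <- featureData(parcels)$parcel_id
  ord <- order(ids)
  geoms <- geoms[ord]; ids <- ids[ord]
  comp <- componentsByDistance(geoms, 2 * gap_fill)
  parts <- list(); partComp <- integer(0L); partId <- character(0L)
  for (i in seq_along(geoms)) {
    for (m in geoms[[i]]$parts) {
      parts[[length(parts) + 1L]] <- m
      partComp <- c(partComp, comp[i])
      partId <- c(partId, ids[i])
    }
  }
  # parts are usually interior-disjoint parcels, but the union measure must
  # hold even when inputs overlap, so the exact union path is used
  g <- gpoly(parts, disjoint = FALSE)
  attr(g, "components") <- partComp
  attr(g, "parcel_id") <- partId
  g
}

#' Number of connected components of a dissolved region
#' @param g a `gpoly` from [dissolveParcels()], or any `gpoly` (then
#'   computed at gap 0).
#' @return integer component count.
#' @export
nComponents <- function(g) {
  comp <- attr(g, "components")
  if (!is.null(comp)) return(length(unique(comp)))
  length(unique(componentsByDistance(lapply(g$parts, gpoly), 0)))
}

#' Normalize a street address for matching
#'
#' Uppercases, strips punctuation, and collapses whitespace.
#' @param x character vector of addresses.
#' @return normalized character vector.
#' @export
normalizeAddress <- function(x) {
  x <- toupper(as.character(x))
  x <- gsub("[^A-Z0-9 ]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Match a billing address list against parcels
#'
#' Exact string equality after normalization; each address matches at most
#' one parcel (the first by parcel id), and unmatched addresses are
#' reported, never dropped.
#'
#' @param addresses character vector of addresses to match.
#' @param parcels a `ParcelSet` carrying an `address` attribute.
#' @return list with `matched` (a `ParcelSet` of hit parcels, ordered by
#'   parcel id) and `unmatched` (character vector of input addresses).
#' @export
matchAddressList <- function(addresses, parcels) {
  fd <- featureData(parcels)
  if (length(addresses) == 0L || nFeatures(parcels) == 0L)
    return(list(matched = subsetFeatures(parcels, integer(0L)),
                unmatched = as.character(addresses)))
  normP <- normalizeAddress(fd$address)
  normP[is.na(fd$address)] <- NA_character_
  ord <- order(fd$parcel_id)
  lookup <- ord[!is.na(normP[ord]) & !duplicated(normP[ord])]
  names(lookup) <- normP[lookup]
  normA <- normalizeAddress(addresses)
  hit <- lookup[normA]
  unmatched <- addresses[is.na(hit)]
  idx <- sort(unique(hit[!is.na(hit)]))
  list(matched = subsetFeatures(parcels, idx), unmatched = unmatched)
}

#' Select parcels adjacent to sewer mains or near manholes
#'
#' A parcel is selected when its boundary-to-boundary distance to any main
#' is at most `main_buffer` (equivalently, it intersects the buffered main)
#' or its distance to any manhole is at most `manhole_radius`.  Thresholds
#' are closed: a parcel exactly at the limit is selected.
#'
#' @param parcels a `ParcelSet`.
#' @param manholes an n x 2 matrix of manhole points (or NULL).
#' @param mains a list of polyline matrices (or NULL).
#' @param config a [builderConfig()].
#' @return a `ParcelSet` of selected parcels, ordered by parcel id.
#' @export
selectByInfrastructure <- function(parcels, manholes = NULL, mains = NULL,
                                   config = builderConfig()) {
  nm <- if (is.null(manholes)) 0L else nrow(manholes)
  nl <- if (is.null(mains)) 0L else length(mains)
  if (nm == 0L && nl == 0L)
    emptyInputError("selectByInfrastructure: both manholes and mains are empty")
  geoms <- geometry(parcels)
  sel <- logical(nFeatures(parcels))
  for (i in seq_along(geoms)) {
    g <- geoms[[i]]
    bb <- gpBBox(g)
    if (nm > 0L) {
      r <- config$manhole_radius
      cand <- which(manholes[, 1L] >= bb[1L] - r & manholes[, 1L] <= bb[3L] + r &
                    manholes[, 2L] >= bb[2L] - r & manholes[, 2L] <= bb[4L] + r)
      for (k in cand) {
        if (gpPointDistance(g, manholes[k, ]) <= r) { sel[i] <- TRUE; break }
      }
    }
    if (!sel[i] && nl > 0L) {
      for (ln in mains) {
        lb <- .bboxRing(ln)
        if (!.bboxOverlap(bb, lb, pad = config$main_buffer)) next
        if (gpLineDistance(g, ln) <= config$main_buffer) { sel[i] <- TRUE; break }
      }
    }
  }
  idx <- which(sel)
  idx <- idx[order(featureData(parcels)$parcel_id[idx])]
  subsetFeatures(parcels, idx)
}

#' Select parcels within a boundary polygon
#'
#' Membership by representative interior point (default) or by
#' majority-of-area overlap.
#'
#' @param parcels a `ParcelSet`.
#' @param boundary a `gpoly`.
#' @param config a [builderConfig()]; its `membership` field selects the rule.
#' @return a `ParcelSet` of parcels inside the boundary, ordered by parcel id.
#' @export
selectWithinBoundary <- function(parcels, boundary, config = builderConfig()) {
  .checkBoundary(boundary)
  geoms <- geometry(parcels)
  bb <- gpBBox(boundary)
  sel <- vapply(geoms, function(g) {
    if (!.bboxOverlap(gpBBox(g), bb)) return(FALSE)
    if (config$membership == "area_majority") {
      gpIntersectionArea(g, boundary) > 0.5 * gpArea(g)
    } else {
      all(gpContains(boundary, matrix(gpInteriorPoint(g), ncol = 2L)))
    }
  }, TRUE)
  idx <- which(sel)
  idx <- idx[order(featureData(parcels)$parcel_id[idx])]
  subsetFeatures(parcels, idx)
}

#' Cluster public-sewer parcels and assign clusters to plants
#'
#' Parcels on public sewer are linked into connected components wherever
#' their boundary-to-boundary distance is at most `cluster_gap`; each
#' component goes to the plant nearest to it (a component containing a
#' plant's point goes to that plant regardless of distance), ties broken by
#' lowest plant id.
#'
#' @param parcels a `ParcelSet`; only `sewer_flag == "public"` rows are used.
#' @param plants a `PlantSet` with at least one plant.
#' @param config a [builderConfig()].
#' @return named list, one `ParcelSet` per plant id (possibly empty).
#' @export
clusterAndAssign <- function(parcels, plants, config = builderConfig()) {
  pd <- featureData(plants)
  if (nrow(pd) == 0L) configError("clusterAndAssign: no plants")
  pubIdx <- which(featureData(parcels)$sewer_flag == "public")
  plantOrder <- order(pd$plant_id)
  out <- stats::setNames(vector("list", nrow(pd)), pd$plant_id[plantOrder])
  for (k in seq_along(out)) out[[k]] <- subsetFeatures(parcels, integer(0L))
  if (length(pubIdx) == 0L) return(out)
  pub <- subsetFeatures(parcels, pubIdx)
  geoms <- geometry(pub)
  comp <- componentsByDistance(geoms, config$cluster_gap)
  sites <- cbind(pd$x, pd$y)[plantOrder, , drop = FALSE]
  pids <- pd$plant_id[plantOrder]
  for (cid in sort(unique(comp))) {
    members <- which(comp == cid)
    # containment override: a component holding a plant point belongs to it
    owner <- NA_integer_
    for (k in seq_along(pids)) {
      pt <- matrix(sites[k, ], ncol = 2L)
      if (any(vapply(geoms[members], function(g) gpContains(g, pt), TRUE))) {
        owner <- k; break
      }
    }
    if (is.na(owner)) {
      d <- vapply(seq_along(pids), function(k) {
        min(vapply(geoms[members], gpPointDistance, 0, p = sites[k, ]))
      }, 0)
      owner <- which.min(d)              # first minimum = lowest plant_id
    }
    cur <- featureData(out[[owner]])$parcel_id
    ids <- featureData(pub)$parcel_id[members]
    keep <- which(featureData(pub)$parcel_id %in% c(cur, ids))
    out[[owner]] <- subsetFeatures(pub, keep[order(featureData(pub)$parcel_id[keep])])
  }
  out
}

#' Split parcels into systems by sewer district, with clustering fallback
#'
#' Parcels carrying a district label are routed to plants through
#' `district_to_plant`; parcels without a label fall back to
#' [clusterAndAssign()] and are flagged.
#'
#' @param parcels a `ParcelSet`; only public-sewer rows are used.
#' @param plants a `PlantSet`.
#' @param district_to_plant named character vector, district id to plant id;
#'   must cover every district observed on the parcels.
#' @param config a [builderConfig()].
#' @return list with `assignments` (named list of `ParcelSet` per plant)
#'   and `flagged` (parcel ids assigned by the clustering fallback).
#' @export
splitByDistrict <- function(parcels, plants, district_to_plant,
                            config = builderConfig()) {
  pd <- featureData(plants)
  if (nrow(pd) == 0L) configError("splitByDistrict: no plants")
  fd <- featureData(parcels)
  pubIdx <- which(fd$sewer_flag == "public")
  pub <- subsetFeatures(parcels, pubIdx)
  fdp <- featureData(pub)
  seen <- unique(fdp$district[!is.na(fdp$district)])
  missing <- setdiff(seen, names(district_to_plant))
  if (length(missing))
    referenceError(paste("unresolved sewer district(s):",
                         paste(sort(missing), collapse = ", ")),
                   districts = sort(missing))
  plantOrder <- order(pd$plant_id)
  out <- stats::setNames(vector("list", nrow(pd)), pd$plant_id[plantOrder])
  for (k in seq_along(out)) out[[k]] <- subsetFeatures(parcels, integer(0L))
  labelled <- which(!is.na(fdp$district))
  for (pid in names(out)) {
    d_here <- names(district_to_plant)[district_to_plant == pid]
    idx <- labelled[fdp$district[labelled] %in% d_here]
    out[[pid]] <- subsetFeatures(pub, idx[order(fdp$parcel_id[idx])])
  }
  flagged <- character(0L)
  resid <- which(is.na(fdp$district))
  if (length(resid)) {
    fb <- clusterAndAssign(subsetFeatures(pub, resid), plants, config)
    for (pid in names(fb)) {
      add <- featureData(fb[[pid]])$parcel_id
      if (length(add) == 0L) next
      flagged <- c(flagged, add)
      ids <- c(featureData(out[[pid]])$parcel_id, add)
      keep <- which(fdp$parcel_id %in% ids)
      out[[pid]] <- subsetFeatures(pub, keep[order(fdp$parcel_id[keep])])
    }
  }
  list(assignments = out, flagged = sort(flagged))
}

#' Augment a provided boundary with adjacent public parcels
#'
#' Unions the boundary with every public-sewer parcel that intersects it or
#' lies within `cluster_gap` of it; the result always contains the input
#' boundary.
#'
#' @param boundary a `gpoly`.
#' @param parcels a `ParcelSet`; only public rows are candidates.
#' @param config a [builderConfig()].
#' @return a `gpoly` (parts may overlap; its area is the exact union
#'   measure) with attribute `parcel_id` listing the added parcels.
#' @export
mergeBoundaryWithParcels <- function(boundary, parcels,
                                     config = builderConfig()) {
  .checkBoundary(boundary)
  fd <- featureData(parcels)
  pubIdx <- which(fd$sewer_flag == "public")
  geoms <- geometry(parcels)
  bb <- gpBBox(boundary)
  added <- pubIdx[vapply(pubIdx, function(i) {
    if (!.bboxOverlap(gpBBox(geoms[[i]]), bb, pad = config$cluster_gap))
      return(FALSE)
    gpDistance(geoms[[i]], boundary) <= config$cluster_gap
  }, TRUE)]
  added <- added[order(fd$parcel_id[added])]
  parts <- boundary$parts
  for (i in added) parts <- c(parts, geoms[[i]]$parts)
  g <- gpoly(parts, disjoint = length(added) == 0L && boundary$disjoint)
  attr(g, "parcel_id") <- fd$parcel_id[added]
  g
}

.newShed <- function(shed_id, plant_id, geom, method, members = character(0L)) {
  list(shed_id = shed_id, plant_id = plant_id, geometry = geom,
       method = method, members = members)
}

#' Build sewersheds for every plant from the best available data
#'
#' Applies, per plant, the first applicable workflow in priority order:
#' `provided` (boundary used verbatim), `danc_merge` (provided boundary
#' augmented with adjacent public parcels), `address_list`,
#' `infrastructure` (manholes/mains proximity), `physical_map` (parcels
#' within a supplied boundary), then — for all remaining plants jointly —
#' `parcel_district` (when a district map is supplied) and
#' `parcel_cluster`, and finally `village_fallback` (a supplied village
#' polygon used verbatim as a placeholder).  Parcels claimed by an earlier
#' workflow are withdrawn from the pool, so each public parcel ends up in
#' at most one sewershed.  All parcel-derived geometries pass through
#' [dissolveParcels()].
#'
#' @param parcels a `ParcelSet` of the study area.
#' @param plants a `PlantSet`.
#' @param config a [builderConfig()].
#' @param provided named list (by plant id) of `gpoly` boundaries, or a
#'   list of boundaries per plant for multi-influent facilities.
#' @param dancBoundaries named list of `gpoly` boundaries to augment.
#' @param addressLists named list of character address vectors.
#' @param infrastructure named list of `list(manholes =, mains =)`.
#' @param mapBoundaries named list of `gpoly` physical-map boundaries.
#' @param districtMap named character vector, district id to plant id
#'   (NULL when no district data exist).
#' @param villages named list of `gpoly` village polygons.
#' @return a `SewershedSet`; the per-shed construction method is recorded
#'   in its `method` column, and fallback-flagged parcels in the
#'   `flagged_parcels` attribute.
#' @export
buildSewersheds <- function(parcels, plants, config = builderConfig(),
                            provided = list(), dancBoundaries = list(),
                            addressLists = list(), infrastructure = list(),
                            mapBoundaries = list(), districtMap = NULL,
                            villages = list()) {
  pd <- featureData(plants)
  if (nrow(pd) == 0L) configError("buildSewersheds: no plants")
  plantIds <- sort(pd$plant_id)
  pool <- subsetFeatures(parcels, order(featureData(parcels)$parcel_id))
  sheds <- list()
  flagged <- character(0L)
  unresolved <- character(0L)

  claim <- function(ids) {
    keep <- which(!(featureData(pool)$parcel_id %in% ids))
    pool <<- subsetFeatures(pool, keep)
  }
  addShed <- function(...) sheds[[length(sheds) + 1L]] <<- .newShed(...)

  resolved <- character(0L)
  for (pid in plantIds) {
    if (!is.null(provided[[pid]])) {
      bs <- provided[[pid]]
      if (is.gpoly(bs)) bs <- list(bs)
      for (k in seq_along(bs)) {
        .checkBoundary(bs[[k]])
        inside <- selectWithinBoundary(pool, bs[[k]], config)
        ids <- featureData(inside)$parcel_id
        claim(ids)
        sid <- if (length(bs) > 1L) sprintf("SH_%s_%d", pid, k) else sprintf("SH_%s", pid)
        addShed(sid, pid, bs[[k]], "provided", ids)
      }
      resolved <- c(resolved, pid)
    } else if (!is.null(dancBoundaries[[pid]])) {
      g <- mergeBoundaryWithParcels(dancBoundaries[[pid]], pool, config)
      ids <- attr(g, "parcel_id")
      # parcels inside the original boundary are part of the system too
      inside <- selectWithinBoundary(pool, dancBoundaries[[pid]], config)
      ids <- sort(unique(c(ids, featureData(inside)$parcel_id)))
      claim(ids)
      addShed(sprintf("SH_%s", pid), pid, g, "danc_merge", ids)
      resolved <- c(resolved, pid)
    } else if (!is.null(addressLists[[pid]])) {
      m <- matchAddressList(addressLists[[pid]], pool)
      if (nFeatures(m$matched) > 0L) {
        ids <- featureData(m$matched)$parcel_id
        g <- dissolveParcels(m$matched, config$dissolve_gap_fill)
        claim(ids)
        addShed(sprintf("SH_%s", pid), pid, g, "address_list", ids)
        resolved <- c(resolved, pid)
      }
    } else if (!is.null(infrastructure[[pid]])) {
      inf <- infrastructure[[pid]]
      selp <- selectByInfrastructure(pool, inf$manholes, inf$mains, config)
      if (nFeatures(selp) > 0L) {
        ids <- featureData(selp)$parcel_id
        g <- dissolveParcels(selp, config$dissolve_gap_fill)
        claim(ids)
        addShed(sprintf("SH_%s", pid), pid, g, "infrastructure", ids)
        resolved <- c(resolved, pid)
      }
    } else if (!is.null(mapBoundaries[[pid]])) {
      selp <- selectWithinBoundary(pool, mapBoundaries[[pid]], config)
      if (nFeatures(selp) > 0L) {
        ids <- featureData(selp)$parcel_id
        g <- dissolveParcels(selp, config$dissolve_gap_fill)
        claim(ids)
        addShed(sprintf("SH_%s", pid), pid, g, "physical_map", ids)
        resolved <- c(resolved, pid)
      }
    }
  }

  remaining <- setdiff(plantIds, resolved)
  if (length(remaining)) {
    remPlants <- subsetFeatures(plants, which(pd$plant_id %in% remaining))
    if (!is.null(districtMap)) {
      sp <- splitByDistrict(pool, remPlants, districtMap, config)
      flagged <- sp$flagged
      for (pid in remaining) {
        ps <- sp$assignments[[pid]]
        if (nFeatures(ps) > 0L) {
          ids <- featureData(ps)$parcel_id
          method <- if (pid %in% districtMap && any(ids %in% setdiff(ids, flagged)))
            "parcel_district" else "parcel_cluster"
          g <- dissolveParcels(ps, config$dissolve_gap_fill)
          claim(ids)
          addShed(sprintf("SH_%s", pid), pid, g, method, ids)
          resolved <- c(resolved, pid)
        }
      }
    } else {
      ca <- clusterAndAssign(pool, remPlants, config)
      for (pid in remaining) {
        ps <- ca[[pid]]
        if (nFeatures(ps) > 0L) {
          ids <- featureData(ps)$parcel_id
          g <- dissolveParcels(ps, config$dissolve_gap_fill)
          claim(ids)
          addShed(sprintf("SH_%s", pid), pid, g, "parcel_cluster", ids)
          resolved <- c(resolved, pid)
        }
      }
    }
  }

  for (pid in setdiff(plantIds, resolved)) {
    if (!is.null(villages[[pid]])) {
      addShed(sprintf("SH_%s", pid), pid, villages[[pid]], "village_fallback")
      resolved <- c(resolved, pid)
    } else unresolved <- c(unresolved, pid)
  }
  if (length(unresolved))
    configError(paste("unresolvable plant(s), no applicable method and no village polygon:",
                      paste(unresolved, collapse = ", ")),
                plants = unresolved)

  ord <- order(vapply(sheds, `[[`, "", "shed_id"))
  sheds <- sheds[ord]
  res <- SewershedSet(shed_id = vapply(sheds, `[[`, "", "shed_id"),
                      plant_id = vapply(sheds, `[[`, "", "plant_id"),
                      geometry = lapply(sheds, `[[`, "geometry"),
                      method = vapply(sheds, `[[`, "", "method"),
                      members = lapply(sheds, `[[`, "members"))
  attr(res, "flagged_parcels") <- flagged
  res
}
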