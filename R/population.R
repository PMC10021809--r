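# Area-weighted census apportionment and growth projection.
#
# A sewershed's 2010 population is the sum over intersected census blocks
# of block population times the fraction of the block's area falling inside
# the sewershed (uniform density within units).  The same overlay on block
# groups at the 2010 and 2018 vintages gives the annual growth rate
#   rate = ((pop2018 - pop2010) / pop2010) / 8
# which is applied to the block-based 2010 figure over ten years,
#   pop2020 = pop2010_block * (1 + rate)^10.
# Fractional persons are retained throughout; rounding is an output option.

.SLIVER_TOL <- 1e-9   # of unit area: smaller overlaps are numerical noise

#' Area-overlap weights of census units against a sewershed
#'
#' One weight per unit with positive intersection: intersection area over
#' unit area, in `[0, 1]`.  Overlaps below `1e-9` of the unit area are
#' dropped as slivers.  Output is ordered by unit id.
#'
#' @param sewershed a `gpoly`, or a single-row `SewershedSet`.
#' @param units a `CensusLayer`.
#' @return data.frame with columns `unit_id` and `weight`.
#' @export
intersectWeights <- function(sewershed, units) {
  g <- if (is.gpoly(sewershed)) sewershed
       else if (is(sewershed, "SewershedSet") && nFeatures(sewershed) == 1L)
         geometry(sewershed)[[1L]]
       else geometryError("sewershed must be a gpoly or a single-row SewershedSet")
  fd <- featureData(units)
  geoms <- geometry(units)
  bb <- gpBBox(g)
  ids <- character(0L); w <- numeric(0L)
  for (i in seq_along(geoms)) {
    if (!.bboxOverlap(gpBBox(geoms[[i]]), bb)) next
    ua <- gpArea(geoms[[i]])
    if (ua <= 0)
      geometryError(paste("census unit has no area:", fd$unit_id[i]))
    ia <- gpIntersectionArea(g, geoms[[i]])
    if (ia <= .SLIVER_TOL * ua) next
    ids <- c(ids, fd$unit_id[i])
    w <- c(w, min(ia / ua, 1))
  }
  ord <- order(ids)
  data.frame(unit_id = ids[ord], weight = w[ord], stringsAsFactors = FALSE)
}

#' Apportion unit populations through overlap weights
#'
#' @param weights data.frame from [intersectWeights()].
#' @param units the `CensusLayer` the weights refer to.
#' @return total apportioned persons (fractional).
#' @export
apportion <- function(weights, units) {
  if (nrow(weights) == 0L) return(0)
  fd <- featureData(units)
  idx <- match(weights$unit_id, fd$unit_id)
  if (anyNA(idx))
    referenceError(paste("unknown unit id(s):",
                         paste(weights$unit_id[is.na(idx)], collapse = ", ")))
  sum(weights$weight * fd$pop[idx])
}

#' Annual population growth rate from two vintages
#'
#' `((pop2018 - pop2010) / pop2010) / 8` per year.  A zero 2010 base gives
#' rate 0 with a `zero_base` flag instead of an error; a rate at or below
#' -1/8 per year (total loss within the eight-year window) is returned
#' as-is with a `collapse` flag.
#'
#' @param pop2010,pop2018 non-negative person counts.
#' @return numeric rate with a character `flags` attribute.
#' @export
annualGrowthRate <- function(pop2010, pop2018) {
  if (pop2010 < 0 || pop2018 < 0)
    domainError("populations must be non-negative")
  if (pop2010 == 0)
    return(structure(0, flags = "zero_base"))
  r <- ((pop2018 - pop2010) / pop2010) / 8
  structure(r, flags = if (r <= -1 / 8) "collapse" else character(0L))
}

#' Ten-year compound projection
#'
#' `pop2010 * (1 + rate)^10`.
#'
#' @param pop2010_block persons (block-based 2010 figure).
#' @param rate per-year fraction, must exceed -1.
#' @return projected persons.
#' @export
project2020 <- function(pop2010_block, rate) {
  if (pop2010_block < 0) domainError("population must be non-negative")
  if (rate <= -1)
    domainError(sprintf("projection undefined for rate <= -1 (got %g)", rate))
  pop2010_block * (1 + rate)^10
}

#' Estimate populations for every sewershed
#'
#' Per sewershed: block apportionment of the 2010 decennial population;
#' block-group apportionment at the 2010 and 2018 vintages; the annual
#' growth rate from the block-group pair; and the ten-year projection
#' applied to the block-based figure.  Density (pop2020 / area) and area
#' are carried through for quality assurance.
#'
#' @param sewersheds a `SewershedSet`.
#' @param blocks2010 `CensusLayer` of 2010 blocks.
#' @param bg2010,bg2018 `CensusLayer` block groups at the two vintages.
#' @param round_outputs round person counts in the result?
#' @return data.frame with one row per sewershed: `shed_id`, `plant_id`,
#'   `method`, `pop10_blk`, `pop10_bg`, `pop18_bg`, `rate`, `pop2020`,
#'   `area`, `density`, `flags` (';'-joined quality flags).
#' @export
estimateAll <- function(sewersheds, blocks2010, bg2010, bg2018,
                        round_outputs = FALSE) {
  sd <- featureData(sewersheds)
  geoms <- geometry(sewersheds)
  n <- nrow(sd)
  out <- data.frame(shed_id = sd$shed_id, plant_id = sd$plant_id,
                    method = sd$method,
                    pop10_blk = numeric(n), pop10_bg = numeric(n),
                    pop18_bg = numeric(n), rate = numeric(n),
                    pop2020 = numeric(n), area = sd$area,
                    density = numeric(n), flags = character(n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    res <- tryCatch({
      wb <- intersectWeights(geoms[[i]], blocks2010)
      wg10 <- intersectWeights(geoms[[i]], bg2010)
      wg18 <- intersectWeights(geoms[[i]], bg2018)
      p10b <- apportion(wb, blocks2010)
      p10g <- apportion(wg10, bg2010)
      p18g <- apportion(wg18, bg2018)
      r <- annualGrowthRate(p10g, p18g)
      p20 <- project2020(p10b, as.numeric(r))
      list(p10b = p10b, p10g = p10g, p18g = p18g,
           r = as.numeric(r), p20 = p20, flags = attr(r, "flags"))
    }, sewersheds_error = function(e) {
      stop(errorCondition(
        sprintf("sewershed %s: %s", sd$shed_id[i], conditionMessage(e)),
        class = class(e)))
    })
    out$pop10_blk[i] <- res$p10b
    out$pop10_bg[i] <- res$p10g
    out$pop18_bg[i] <- res$p18g
    out$rate[i] <- res$r
    out$pop2020[i] <- res$p20
    out$density[i] <- res$p20 / sd$area[i]
    out$flags[i] <- paste(res$flags, collapse = ";")
  }
  if (round_outputs) {
    for (col in c("pop10_blk", "pop10_bg", "pop18_bg", "pop2020"))
      out[[col]] <- round(out[[col]])
  }
  out
}
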