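# Synthetic-geography generator.
#
# Produces self-consistent synthetic counties with the statistical structure
# the downstream analysis assumes: a rectangular region tiled by census
# blocks nested exactly into block groups; treatment plants with log-normal
# (base-10) permitted discharge capacities; ground-truth sewersheds built as
# Voronoi cells of the plant sites clipped to the region and shrunk inward
# by one parcel size (so inter-sewershed gaps exceed any clustering
# threshold); parcels tiling each sewershed with a configurable fraction
# flagged as on public sewer; and populations tied to capacity through
#   log10(pop) = a + b * log10(capacity) + Normal(0, sigma).
# Populations are spread equally over the census blocks that lie fully
# inside a sewershed and whose block group does not straddle two
# sewersheds; all other blocks carry population zero, which makes block
# apportionment and growth-rate recovery exact by construction.  2018
# block-group populations apply each sewershed's planted annual growth rate
# g linearly over eight years: pop2018 = pop2010 * (1 + 8 g).

# distinct substreams per layer so changing one field perturbs only its layer
.layerSeed <- function(seed, k) (as.integer(seed) + k * 1000003L) %% 2147483587L

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Synthetic scene configuration
#'
#' Returns a validated configuration list for [generateScene()].  Defaults
#' describe a small county-like region: a 3000 x 3000 planar region (units
#' read as meters) tiled by 15 x 15 census blocks (200 m squares) nested in
#' block groups of 3 consecutive blocks, five treatment plants with
#' log10-capacity ~ Normal(-0.3, 0.8) in millions of gallons per day
#' (median about 0.5 mgd), population tied to capacity with slope 1 and
#' intercept 4 (so 1 mgd serves about 10,000 people) plus log10 noise 0.12,
#' annual growth rates uniform in [-0.005, 0.02], 60 m parcels with 90% of
#' in-sewershed parcels flagged public, and an urban density threshold of
#' 4e-4 persons per square meter (400 per square km).
#'
#' @param seed integer seed; all layer randomness derives from it.
#' @param region_width,region_height region extent in length units.
#' @param n_blocks_x,n_blocks_y census-block grid dimensions.
#' @param blocks_per_group blocks per block group (must divide the block
#'   count; groups are consecutive runs in row-major order).
#' @param n_plants number of treatment plants.
#' @param capacity_log_mean,capacity_log_sd base-10 log-normal parameters
#'   of permitted discharge capacity (volume/day).
#' @param pop_capacity_slope,pop_capacity_intercept,pop_noise_sd the
#'   log10(pop) ~ log10(capacity) line and its Gaussian noise sd.
#' @param growth_rate_range length-2 interval of per-year growth fractions.
#' @param parcel_size parcel tile edge in length units.
#' @param sewered_fraction_inside fraction in `[0, 1]` of in-sewershed
#'   parcels flagged `public`.
#' @param district_labels_present attach per-system sewer-district labels?
#' @param urban_flag_rule county sewered-density threshold (persons per
#'   squared length unit) above which a county is flagged urban.
#' @param n_counties number of equal vertical county strips.
#' @return a named list of class `SceneConfig`.
#' @export
sceneConfig <- function(seed = 1L,
                        region_width = 3000, region_height = 3000,
                        n_blocks_x = 15L, n_blocks_y = 15L,
                        blocks_per_group = 3L,
                        n_plants = 5L,
                        capacity_log_mean = -0.3, capacity_log_sd = 0.8,
                        pop_capacity_slope = 1.0,
                        pop_capacity_intercept = 4.0,
                        pop_noise_sd = 0.12,
                        growth_rate_range = c(-0.005, 0.02),
                        parcel_size = 60,
                        sewered_fraction_inside = 0.9,
                        district_labels_present = TRUE,
                        urban_flag_rule = 4e-4,
                        n_counties = 2L) {
  cfg <- list(seed = as.integer(seed),
              region_width = region_width, region_height = region_height,
              n_blocks_x = as.integer(n_blocks_x),
              n_blocks_y = as.integer(n_blocks_y),
              blocks_per_group = as.integer(blocks_per_group),
              n_plants = as.integer(n_plants),
              capacity_log_mean = capacity_log_mean,
              capacity_log_sd = capacity_log_sd,
              pop_capacity_slope = pop_capacity_slope,
              pop_capacity_intercept = pop_capacity_intercept,
              pop_noise_sd = pop_noise_sd,
              growth_rate_range = as.numeric(growth_rate_range),
              parcel_size = parcel_size,
              sewered_fraction_inside = sewered_fraction_inside,
              district_labels_present = isTRUE(district_labels_present),
              urban_flag_rule = urban_flag_rule,
              n_counties = as.integer(n_counties))
  counts <- c(cfg$n_blocks_x, cfg$n_blocks_y, cfg$blocks_per_group,
              cfg$n_plants, cfg$n_counties)
  if (any(counts < 1L)) configError("all counts must be >= 1")
  if (cfg$region_width <= 0 || cfg$region_height <= 0)
    configError("region dimensions must be positive")
  if (cfg$pop_noise_sd < 0 || cfg$capacity_log_sd < 0)
    configError("noise standard deviations must be non-negative")
  if (cfg$sewered_fraction_inside < 0 || cfg$sewered_fraction_inside > 1)
    configError("sewered_fraction_inside must be in [0, 1]")
  if ((cfg$n_blocks_x * cfg$n_blocks_y) %% cfg$blocks_per_group != 0L)
    configError("n_blocks_x * n_blocks_y must be divisible by blocks_per_group")
  if (length(cfg$growth_rate_range) != 2L ||
      diff(cfg$growth_rate_range) < 0)
    configError("growth_rate_range must be an ordered length-2 interval")
  if (cfg$parcel_size <= 0) configError("parcel_size must be positive")
  class(cfg) <- c("SceneConfig", "list")
  cfg
}

#' Draw capacities and matched populations
#'
#' The scene's capacity/population model on its own: base-10 log-normal
#' capacities and populations satisfying
#' `log10(pop) = a + b*log10(capacity) + Normal(0, sigma)`.
#'
#' @param n number of plants.
#' @param a,b intercept and slope of the log10 line.
#' @param sigma Gaussian sd of the log10 population noise.
#' @param log_mean,log_sd base-10 log-normal capacity parameters.
#' @param seed integer seed.
#' @return data.frame with columns `capacity` and `pop`.
#' @export
simulateCapacityPopulation <- function(n, a = 4, b = 1, sigma = 0.12,
                                       log_mean = -0.3, log_sd = 0.8,
                                       seed = 1L) {
  stopifnot(n >= 1L, sigma >= 0, log_sd >= 0)
  caps <- .withSeed(.layerSeed(seed, 2L), 10^stats::rnorm(n, log_mean, log_sd))
  eps <- .withSeed(.layerSeed(seed, 3L), stats::rnorm(n, 0, sigma))
  data.frame(capacity = caps, pop = 10^(a + b * log10(caps) + eps))
}

# place plants on a jittered coarse grid so pairwise separations stay large
.placePlants <- function(cfg) {
  p <- cfg$parcel_size
  k <- ceiling(sqrt(cfg$n_plants))
  cw <- cfg$region_width / k
  ch <- cfg$region_height / k
  if (min(cw, ch) < 6 * p)
    configError(sprintf(
      "impossible layout: %d plants need grid cells of at least %g units, region allows %g",
      cfg$n_plants, 6 * p, min(cw, ch)))
  cells <- .withSeed(.layerSeed(cfg$seed, 1L), {
    pick <- sort(sample.int(k * k, cfg$n_plants))
    jx <- stats::runif(cfg$n_plants, -1, 1) * max(0, cw / 2 - 2.5 * p)
    jy <- stats::runif(cfg$n_plants, -1, 1) * max(0, ch / 2 - 2.5 * p)
    list(pick = pick, jx = jx, jy = jy)
  })
  col <- (cells$pick - 1L) %% k
  row <- (cells$pick - 1L) %/% k
  cbind(x = (col + 0.5) * cw + cells$jx,
        y = (row + 0.5) * ch + cells$jy)
}

# tile a convex cell with parcel_size squares clipped to the cell
.tileCell <- function(cell, p, minFrac = 0.05) {
  bb <- gpBBox(cell)
  xs <- seq(floor(bb[1L] / p) * p, bb[3L], by = p)
  ys <- seq(floor(bb[2L] / p) * p, bb[4L], by = p)
  ring <- cell$parts[[1L]]
  out <- list()
  for (y0 in ys) for (x0 in xs) {
    sq <- rbind(c(x0, y0), c(x0 + p, y0), c(x0 + p, y0 + p), c(x0, y0 + p))
    r <- .clipByConvex(sq, ring)
    if (nrow(r) >= 3L && abs(.ringSignedArea(r)) >= minFrac * p * p)
      out[[length(out) + 1L]] <- r
  }
  out
}

#' Generate a synthetic scene
#'
#' @param config a `SceneConfig` from [sceneConfig()].
#' @return a [`SewerScene`][SewerScene-class] with nested census layers at
#'   two vintages, parcels, plants, ground-truth sewersheds, planted
#'   per-plant populations and growth rates, and a county table.
#' @seealso [sceneConfig()], [sceneToDisk()]
#' @export
generateScene <- function(config) {
  if (!inherits(config, "SceneConfig")) configError("config must come from sceneConfig()")
  cfg <- config
  W <- cfg$region_width; H <- cfg$region_height
  np <- cfg$n_plants
  psz <- cfg$parcel_size

  sites <- .placePlants(cfg)
  plant_id <- sprintf("P%02d", seq_len(np))

  cp <- simulateCapacityPopulation(np,
                                   a = cfg$pop_capacity_intercept,
                                   b = cfg$pop_capacity_slope,
                                   sigma = cfg$pop_noise_sd,
                                   log_mean = cfg$capacity_log_mean,
                                   log_sd = cfg$capacity_log_sd,
                                   seed = cfg$seed)
  growth <- .withSeed(.layerSeed(cfg$seed, 4L),
                      stats::runif(np, cfg$growth_rate_range[1L],
                                   cfg$growth_rate_range[2L]))
  names(growth) <- plant_id
  truePop <- cp$pop
  names(truePop) <- plant_id

  # ground-truth sewersheds: Voronoi cells shrunk by one parcel size
  cells <- voronoiCells(sites, c(0, 0, W, H))
  sheds <- lapply(cells, shrinkConvex, d = psz)
  if (any(vapply(sheds, is.null, TRUE)))
    configError("impossible layout: a sewershed emptied under shrinking; reduce n_plants or parcel_size")

  # census blocks (row-major grid) and nested block groups
  nbx <- cfg$n_blocks_x; nby <- cfg$n_blocks_y
  bw <- W / nbx; bh <- H / nby
  nb <- nbx * nby
  bx <- (seq_len(nb) - 1L) %% nbx
  by <- (seq_len(nb) - 1L) %/% nbx
  blockRings <- lapply(seq_len(nb), function(i) {
    x0 <- bx[i] * bw; y0 <- by[i] * bh
    rbind(c(x0, y0), c(x0 + bw, y0), c(x0 + bw, y0 + bh), c(x0, y0 + bh))
  })
  block_id <- sprintf("B%04d", seq_len(nb))
  grp <- (seq_len(nb) - 1L) %/% cfg$blocks_per_group + 1L
  group_id <- sprintf("G%03d", grp)

  # a block is "inside" a shed when all its corners are (sheds are convex)
  blockShed <- rep(NA_integer_, nb)
  for (s in seq_along(sheds)) {
    ring <- sheds[[s]]$parts[[1L]]
    bb <- .bboxRing(ring)
    cand <- which(is.na(blockShed) &
                  bx * bw < bb[3L] & (bx + 1L) * bw > bb[1L] &
                  by * bh < bb[4L] & (by + 1L) * bh > bb[2L])
    for (i in cand) {
      if (all(.pointsInRing(blockRings[[i]][, 1L], blockRings[[i]][, 2L], ring)))
        blockShed[i] <- s
    }
  }
  # feeder groups: groups whose contained blocks all belong to one shed
  feederShed <- vapply(split(blockShed, grp), function(v) {
    u <- unique(v[!is.na(v)])
    if (length(u) == 1L) u else NA_integer_
  }, 0L)
  popShed <- blockShed
  popShed[is.na(feederShed[grp]) | feederShed[grp] != blockShed] <- NA_integer_

  blockPop <- numeric(nb)
  for (s in seq_len(np)) {
    members <- which(!is.na(popShed) & popShed == s)
    if (length(members) == 0L)
      configError(sprintf(
        "impossible layout: sewershed %d contains no whole census block group; use finer blocks", s))
    blockPop[members] <- truePop[s] / length(members)
  }

  blocks2010 <- CensusLayer(block_id, lapply(blockRings, gpoly), blockPop,
                            "dec2010", "block")
  blocks2010@data$true_shed <- ifelse(is.na(popShed), NA_character_,
                                      sprintf("S%02d", popShed))

  gids <- sprintf("G%03d", seq_len(max(grp)))
  bgGeom <- lapply(seq_len(max(grp)), function(g) gpoly(blockRings[grp == g]))
  bgPop10 <- as.numeric(tapply(blockPop, grp, sum))
  factor18 <- ifelse(is.na(popShed), 1, 1 + 8 * growth[ifelse(is.na(popShed), 1L, popShed)])
  bgPop18 <- as.numeric(tapply(blockPop * factor18, grp, sum))
  bg2010 <- CensusLayer(gids, bgGeom, bgPop10, "dec2010", "block_group")
  bg2018 <- CensusLayer(gids, bgGeom, bgPop18, "acs2018", "block_group")
  fs <- ifelse(is.na(feederShed), NA_character_, sprintf("S%02d", feederShed))
  bg2010@data$true_shed <- fs
  bg2018@data$true_shed <- fs

  # parcels: tile each shed, flag sewered_fraction_inside public
  shed_id <- sprintf("S%02d", seq_len(np))
  parcelRings <- list(); pShed <- integer(0L)
  for (s in seq_len(np)) {
    tiles <- .tileCell(sheds[[s]], psz)
    parcelRings <- c(parcelRings, tiles)
    pShed <- c(pShed, rep(s, length(tiles)))
  }
  nin <- length(parcelRings)
  flags <- rep("private", nin)
  streets <- c("MAIN ST", "RIVER RD", "MILL AVE", "LAKE DR", "CHURCH ST")
  addr <- character(nin)
  .withSeed(.layerSeed(cfg$seed, 5L), {
    for (s in seq_len(np)) {
      idx <- which(pShed == s)
      npub <- round(cfg$sewered_fraction_inside * length(idx))
      if (npub > 0L) flags[idx[sample.int(length(idx), npub)]] <- "public"
      addr[idx] <- sprintf("%d %s", seq_along(idx),
                           streets[(s - 1L) %% length(streets) + 1L])
    }
  })
  district <- if (cfg$district_labels_present) sprintf("D%02d", pShed)
              else rep(NA_character_, nin)
  muni <- sprintf("M%02d", pShed)
  pid <- sprintf("%s_%04d", shed_id[pShed], stats::ave(pShed, pShed, FUN = seq_along))

  # unsewered filler parcels in the countryside (coarser tiles, kept only
  # when clear of every sewershed)
  fp <- 3 * psz
  xs <- seq(0, W - fp, by = fp); ys <- seq(0, H - fp, by = fp)
  fillRings <- list()
  shedBB <- lapply(sheds, gpBBox)
  for (y0 in ys) for (x0 in xs) {
    sq <- rbind(c(x0, y0), c(x0 + fp, y0), c(x0 + fp, y0 + fp), c(x0, y0 + fp))
    sqbb <- c(x0, y0, x0 + fp, y0 + fp)
    clear <- TRUE
    for (s in seq_len(np)) {
      if (!.bboxOverlap(sqbb, shedBB[[s]])) next
      r <- .clipByConvex(sq, sheds[[s]]$parts[[1L]])
      if (nrow(r) >= 3L && abs(.ringSignedArea(r)) > 1e-9 * fp * fp) { clear <- FALSE; break }
    }
    if (clear) fillRings[[length(fillRings) + 1L]] <- sq
  }
  nf <- length(fillRings)
  parcels <- ParcelSet(
    parcel_id = c(pid, sprintf("R_%04d", seq_len(nf))),
    geometry = c(lapply(parcelRings, gpoly), lapply(fillRings, gpoly)),
    sewer_flag = c(flags, rep(c("private", "unknown"),
                              length.out = nf)),
    district = c(district, rep(NA_character_, nf)),
    address = c(addr, rep(NA_character_, nf)),
    muni_id = c(muni, rep(NA_character_, nf)))

  # counties: equal vertical strips; urban when sewered density is high
  ncty <- cfg$n_counties
  ctyOf <- pmin(ncty, floor(sites[, 1L] / (W / ncty)) + 1L)
  county_id <- sprintf("C%02d", seq_len(ncty))
  ctyArea <- rep(W / ncty * H, ncty)
  ctyPop <- as.numeric(tapply(truePop[seq_len(np)], factor(ctyOf, levels = seq_len(ncty)), sum))
  ctyPop[is.na(ctyPop)] <- 0
  counties <- data.frame(county_id = county_id,
                         urban = ctyPop / ctyArea >= cfg$urban_flag_rule,
                         pop = ctyPop, area = ctyArea,
                         stringsAsFactors = FALSE)

  plants <- PlantSet(plant_id, sites[, 1L], sites[, 2L], cp$capacity,
                     name = sprintf("Plant %02d", seq_len(np)),
                     avg_flow = ifelse(seq_len(np) %% 2L == 0L,
                                       0.65 * cp$capacity, NA_real_),
                     county_id = county_id[ctyOf])

  trueSheds <- SewershedSet(shed_id, plant_id, sheds,
                            rep("provided", np),
                            members = split(pid, shed_id[pShed])[shed_id])

  new("SewerScene",
      blocks2010 = blocks2010, blockGroups2010 = bg2010,
      blockGroups2018 = bg2018, parcels = parcels, plants = plants,
      trueSewersheds = trueSheds, trueGrowthRates = growth,
      truePopulations = truePop, counties = counties, config = unclass(cfg))
}

#' Ground-truth sewersheds snapped to whole block groups
#'
#' For each plant, the union of the block groups whose populated blocks lie
#' inside its true sewershed.  These block-group-aligned regions nest the
#' census geography exactly, so population apportionment and growth-rate
#' recovery against them are exact; they also partition the populated
#' blocks.
#'
#' @param scene a `SewerScene`.
#' @return a `SewershedSet` (method `provided`), one sewershed per plant.
#' @export
blockGroupAlignedSheds <- function(scene) {
  bg <- scene@blockGroups2010
  fs <- bg@data$true_shed
  plant_id <- featureData(scene@plants)$plant_id
  shed_id <- featureData(scene@trueSewersheds)$shed_id
  geoms <- list(); keep <- character(0L); pids <- character(0L)
  for (i in seq_along(shed_id)) {
    idx <- which(!is.na(fs) & fs == shed_id[i])
    if (length(idx) == 0L) next
    rings <- unlist(lapply(bg@geometry[idx], function(g) g$parts), recursive = FALSE)
    geoms[[length(geoms) + 1L]] <- gpoly(rings)
    keep <- c(keep, shed_id[i]); pids <- c(pids, plant_id[i])
  }
  SewershedSet(keep, pids, geoms, rep("provided", length(keep)))
}
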