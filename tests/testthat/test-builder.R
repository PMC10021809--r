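# Sewershed construction workflows.

test_that("dissolve unions abutting parcels and honours gap_fill closing", {
  two <- ParcelSet(c("a", "b"), list(rectPoly(0, 0, 1, 1), rectPoly(1, 0, 2, 1)),
                   sewer_flag = c("public", "public"))
  d <- dissolveParcels(two)
  expect_equal(gpArea(d), 2)
  expect_equal(nComponents(d), 1L)
  # single parcel: geometry unchanged
  one <- subsetFeatures(two, 1L)
  d1 <- dissolveParcels(one)
  expect_equal(d1$parts, geometry(one)[[1]]$parts)
  # separated squares: gap 0.1 bridged by gap_fill 0.2, not by 0
  sep <- ParcelSet(c("a", "b"), list(rectPoly(0, 0, 1, 1), rectPoly(1.1, 0, 2.1, 1)),
                   sewer_flag = c("public", "public"))
  expect_equal(nComponents(dissolveParcels(sep, gap_fill = 0.2)), 1L)
  d0 <- dissolveParcels(sep, gap_fill = 0)
  expect_equal(nComponents(d0), 2L)
  # independent connectivity oracle on the parts
  expect_equal(length(unique(bruteComponents(lapply(d0$parts, gpoly), 0))), 2L)
  expect_error(dissolveParcels(subsetFeatures(two, integer(0))),
               class = "sewersheds_empty_input_error")
})

test_that("dissolve area conservation: <= sum of areas, equal iff disjoint", {
  disjoint <- parcelGrid(3, 3)
  dd <- dissolveParcels(disjoint)
  expect_equal(gpArea(dd), 9, tolerance = 1e-12)
  overlapping <- ParcelSet(c("a", "b"),
                           list(rectPoly(0, 0, 2, 2), rectPoly(1, 0, 3, 2)),
                           sewer_flag = c("public", "public"))
  dov <- dissolveParcels(overlapping)
  expect_equal(gpArea(dov), 4 + 4 - 2)
  expect_lt(gpArea(dov), 8)
})

test_that("address matching normalizes and reports misses", {
  p <- parcelGrid(2, 1)
  p@data$address <- c("12 MAIN ST", "34 RIVER RD")
  m <- matchAddressList(c("12 Main St."), p)
  expect_equal(featureData(m$matched)$parcel_id, "PC001")
  expect_length(m$unmatched, 0L)
  m2 <- matchAddressList(c("99 Nowhere Rd"), p)
  expect_equal(nFeatures(m2$matched), 0L)
  expect_equal(m2$unmatched, "99 Nowhere Rd")
})

test_that("perturbed addresses all match, agreeing with an all-pairs oracle", {
  set.seed(14)
  n <- 50L
  streets <- c("MAIN ST", "OAK AVE", "RIVER RD", "HILL DR", "LAKE LN")
  base <- sprintf("%d %s", sample(1:999, n), sample(streets, n, replace = TRUE))
  p <- parcelGrid(10, 5)
  p@data$address <- base
  perturb <- function(a) {
    a <- if (runif(1) < 0.5) tolower(a) else a
    if (runif(1) < 0.5) a <- paste0(" ", sub(" ", ",  ", a), ". ")
    a
  }
  queries <- base
  hit <- sample(n, 10)
  queries[hit] <- vapply(base[hit], perturb, "")
  m <- matchAddressList(queries, p)
  expect_equal(nFeatures(m$matched), n)
  expect_length(m$unmatched, 0L)
  # oracle: brute-force normalized comparison over all pairs
  oracle <- vapply(queries, function(q) {
    hits <- which(normalizeAddress(p@data$address) == normalizeAddress(q))
    p@data$parcel_id[hits[1L]]
  }, "")
  expect_setequal(featureData(m$matched)$parcel_id, unname(oracle))
})

test_that("infrastructure selection applies closed distance thresholds", {
  cfg <- builderConfig(main_buffer = 0.5, manhole_radius = 2)
  p <- parcelGrid(1, 1)                       # unit square at origin
  # main passing at distance 0.4 from the parcel edge
  sel <- selectByInfrastructure(p, mains = list(rbind(c(1.4, -1), c(1.4, 2))),
                                config = cfg)
  expect_equal(nFeatures(sel), 1L)
  # manhole just beyond the radius
  sel2 <- selectByInfrastructure(p, manholes = rbind(c(3.01, 0.5)), config = cfg)
  expect_equal(nFeatures(sel2), 0L)
  # manhole exactly at the radius: closed threshold selects
  sel3 <- selectByInfrastructure(p, manholes = rbind(c(3, 0.5)), config = cfg)
  expect_equal(nFeatures(sel3), 1L)
  expect_error(selectByInfrastructure(p, config = cfg),
               class = "sewersheds_empty_input_error")
})

test_that("infrastructure selection matches a brute-force distance oracle", {
  set.seed(77)
  geoms <- lapply(1:200, function(i) {
    x <- runif(1, 0, 50); y <- runif(1, 0, 50)
    rectPoly(x, y, x + 1, y + 1)
  })
  p <- ParcelSet(sprintf("P%03d", 1:200), geoms,
                 sewer_flag = rep("public", 200))
  manholes <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  mains <- list(rbind(c(0, 25), c(50, 26)))
  cfg <- builderConfig(main_buffer = 1.5, manhole_radius = 3)
  sel <- selectByInfrastructure(p, manholes, mains, cfg)
  oracle <- which(vapply(seq_len(200), function(i) {
    dm <- min(vapply(seq_len(nrow(manholes)), function(k)
      gpPointDistance(geoms[[i]], manholes[k, ]), 0))
    dl <- min(vapply(mains, function(l) gpLineDistance(geoms[[i]], l), 0))
    dm <= 3 || dl <= 1.5
  }, TRUE))
  expect_setequal(featureData(sel)$parcel_id, sprintf("P%03d", oracle))
})

test_that("boundary selection: interior-point rule vs area-majority oracle", {
  b <- rectPoly(0, 0, 5, 5)
  inP <- parcelGrid(1, 1, x0 = 1, y0 = 1)
  outP <- parcelGrid(1, 1, x0 = 7, y0 = 7)
  expect_equal(nFeatures(selectWithinBoundary(inP, b)), 1L)
  expect_equal(nFeatures(selectWithinBoundary(outP, b)), 0L)
  expect_error(selectWithinBoundary(inP, gpoly(rbind(c(0, 0), c(1, 0), c(0, 0.0)))),
               class = "sewersheds_geometry_error")
  # straddling parcels on a grid: when overlap exceeds 60% of the parcel,
  # the interior-point decision matches a point-sampling majority oracle
  set.seed(31)
  shifts <- seq(-0.95, 0.95, length.out = 39)   # parcels sliding across x=5
  straddlers <- lapply(shifts, function(s) rectPoly(4.5 + s, 2, 5.5 + s, 3))
  ps <- ParcelSet(sprintf("S%02d", seq_along(shifts)), straddlers,
                  sewer_flag = rep("public", length(shifts)))
  sel <- featureData(selectWithinBoundary(ps, b))$parcel_id
  fr <- vapply(straddlers, function(g)
    mcAreaFraction(b, gpBBox(g), n = 2e4), 0)
  big <- which(fr > 0.6)                        # majority clearly inside
  agree <- mean(sprintf("S%02d", big) %in% sel)
  expect_gte(agree, 0.95)
  # area-majority switch agrees with the oracle on clear majorities too
  cfgM <- builderConfig(membership = "area_majority")
  selM <- featureData(selectWithinBoundary(ps, b, cfgM))$parcel_id
  expect_gte(mean(sprintf("S%02d", big) %in% selM), 0.95)
})

test_that("clustering assigns components to plants like exhaustive search", {
  cfg <- builderConfig(cluster_gap = 1)
  # three clusters, two plants
  g1 <- parcelGrid(2, 2, x0 = 0, y0 = 0)
  g2 <- parcelGrid(2, 2, x0 = 10, y0 = 0, prefix = "QD")
  g3 <- parcelGrid(2, 2, x0 = 20, y0 = 0, prefix = "RD")
  all <- ParcelSet(c(featureData(g1)$parcel_id, featureData(g2)$parcel_id,
                     featureData(g3)$parcel_id),
                   c(geometry(g1), geometry(g2), geometry(g3)),
                   sewer_flag = rep("public", 12))
  plants <- PlantSet(c("P1", "P2"), x = c(1, 21), y = c(5, 5),
                     capacity = c(1, 1))
  res <- clusterAndAssign(all, plants, cfg)
  # oracle: enumerate component-plant distances
  comp <- componentsByDistance(geometry(all), 1)
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    d <- vapply(1:2, function(k)
      min(vapply(geometry(all)[members], gpPointDistance, 0,
                 p = c(c(1, 21)[k], 5))), 0)
    best <- c("P1", "P2")[which.min(d)]
    expect_true(all(featureData(all)$parcel_id[members] %in%
                    featureData(res[[best]])$parcel_id))
  }
  # every public parcel assigned exactly once
  assigned <- unlist(lapply(res, function(s) featureData(s)$parcel_id))
  expect_setequal(assigned, featureData(all)$parcel_id)
  expect_equal(anyDuplicated(assigned), 0L)
})

test_that("a component containing a plant point belongs to that plant", {
  cfg <- builderConfig(cluster_gap = 1)
  gA <- parcelGrid(2, 2, x0 = 0, y0 = 0)
  gB <- parcelGrid(2, 2, x0 = 10, y0 = 0, prefix = "QD")
  all <- ParcelSet(c(featureData(gA)$parcel_id, featureData(gB)$parcel_id),
                   c(geometry(gA), geometry(gB)),
                   sewer_flag = rep("public", 8))
  # P2 sits inside cluster A even though P1 is nearer to A's edge
  plants <- PlantSet(c("P1", "P2"), x = c(2.6, 1), y = c(1, 1),
                     capacity = c(1, 1))
  res <- clusterAndAssign(all, plants, cfg)
  expect_setequal(featureData(res$P2)$parcel_id, featureData(gA)$parcel_id)
  expect_setequal(featureData(res$P1)$parcel_id, featureData(gB)$parcel_id)
  expect_error(clusterAndAssign(all, subsetFeatures(plants, integer(0)), cfg),
               class = "sewersheds_config_error")
  # no public parcels: empty map, not an error
  priv <- ParcelSet("z", list(rectPoly(0, 0, 1, 1)), sewer_flag = "private")
  empty <- clusterAndAssign(priv, plants, cfg)
  expect_equal(sum(vapply(empty, nFeatures, 0L)), 0L)
})

test_that("district split separates systems clustering cannot", {
  cfg <- builderConfig(cluster_gap = 50)
  # two interleaved rows of parcels 10 apart: one distance cluster
  rowA <- parcelGrid(6, 1, size = 8, x0 = 0, y0 = 0)
  rowB <- parcelGrid(6, 1, size = 8, x0 = 0, y0 = 18, prefix = "QD")
  ids <- c(featureData(rowA)$parcel_id, featureData(rowB)$parcel_id)
  par <- ParcelSet(ids, c(geometry(rowA), geometry(rowB)),
                   sewer_flag = rep("public", 12),
                   district = rep(c("D1", "D2"), each = 6))
  plants <- PlantSet(c("P1", "P2"), x = c(24, 24), y = c(-5, 31),
                     capacity = c(1, 1))
  # distance clustering alone merges the two systems
  merged <- clusterAndAssign(par, plants, cfg)
  expect_true(any(vapply(merged, nFeatures, 0L) == 12L))
  # district split recovers the planted partition exactly
  sp <- splitByDistrict(par, plants, c(D1 = "P1", D2 = "P2"), cfg)
  expect_setequal(featureData(sp$assignments$P1)$parcel_id,
                  featureData(rowA)$parcel_id)
  expect_setequal(featureData(sp$assignments$P2)$parcel_id,
                  featureData(rowB)$parcel_id)
  expect_length(sp$flagged, 0L)
  # unmapped district errors with the district named
  expect_error(splitByDistrict(par, plants, c(D1 = "P1"), cfg),
               "D2", class = "sewersheds_reference_error")
  # unlabeled parcels fall back to clustering and are flagged
  par2 <- par
  par2@data$district[12] <- NA
  sp2 <- splitByDistrict(par2, plants, c(D1 = "P1", D2 = "P2"), cfg)
  expect_equal(sp2$flagged, ids[12])
})

test_that("boundary augmentation adds adjacent public parcels only", {
  cfg <- builderConfig(cluster_gap = 0.5)
  b <- rectPoly(0, 0, 4, 4)
  near <- rectPoly(4.2, 0, 5.2, 1)      # within 0.5
  far <- rectPoly(9, 9, 10, 10)
  overl <- rectPoly(3, 3, 5, 5)         # overlaps the boundary
  privAdj <- rectPoly(4.1, 2, 5.1, 3)   # adjacent but private
  par <- ParcelSet(c("n", "f", "o", "pv"), list(near, far, overl, privAdj),
                   sewer_flag = c("public", "public", "public", "private"))
  g <- mergeBoundaryWithParcels(b, par, cfg)
  expect_setequal(attr(g, "parcel_id"), c("n", "o"))
  # inclusion-exclusion: boundary + near + overlap - shared area
  expect_equal(gpArea(g), 16 + 1 + 4 - 1)
  expect_gte(gpIntersectionArea(g, b), gpArea(b) - 1e-9)   # contains input
  # no adjacent parcels: boundary unchanged
  g0 <- mergeBoundaryWithParcels(b, subsetFeatures(par, 2L), cfg)
  expect_equal(gpArea(g0), 16)
  expect_length(attr(g0, "parcel_id"), 0L)
})

test_that("build hierarchy picks the best method and partitions parcels", {
  sc <- smallScene()
  parcels <- sceneParcels(sc)
  plants <- scenePlants(sc)
  cfg <- builderConfig()
  trueG <- geometry(sceneTrueSewersheds(sc))
  pids <- featureData(plants)$plant_id

  # provided boundary wins and passes through verbatim
  sheds <- buildSewersheds(parcels, plants, cfg,
                           provided = stats::setNames(trueG[1], pids[1]))
  sd <- featureData(sheds)
  expect_equal(sd$method[sd$plant_id == pids[1]], "provided")
  expect_identical(geometry(sheds)[[which(sd$plant_id == pids[1])]]$parts,
                   trueG[[1]]$parts)
  # the rest fall through to the parcel tier
  expect_true(all(sd$method[sd$plant_id != pids[1]] %in%
                  c("parcel_district", "parcel_cluster")))

  # clustering-only: every public parcel lands in exactly one member list
  shedsC <- buildSewersheds(parcels, plants, cfg)
  fd <- featureData(parcels)
  assigned <- unlist(shedsC@members)
  pubIds <- fd$parcel_id[fd$sewer_flag == "public"]
  expect_true(all(pubIds %in% assigned))
  expect_equal(anyDuplicated(assigned), 0L)

  # determinism including ordering
  shedsC2 <- buildSewersheds(parcels, plants, cfg)
  expect_identical(featureData(shedsC), featureData(shedsC2))
  expect_identical(shedsC@members, shedsC2@members)
})

test_that("village fallback is used last and unresolvable plants error", {
  par <- parcelGrid(2, 2)                         # far from the plant
  par@data$sewer_flag[] <- "private"              # nothing to cluster
  plants <- PlantSet("P9", x = 100, y = 100, capacity = 2)
  village <- rectPoly(90, 90, 110, 110)
  sheds <- buildSewersheds(par, plants, builderConfig(),
                           villages = list(P9 = village))
  expect_equal(featureData(sheds)$method, "village_fallback")
  expect_identical(geometry(sheds)[[1]]$parts, village$parts)
  expect_error(buildSewersheds(par, plants, builderConfig()),
               class = "sewersheds_config_error")
})
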