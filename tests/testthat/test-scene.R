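# Synthetic scene generator: structure, nesting, planted truth, determinism.

test_that("config validation rejects impossible setups", {
  expect_error(sceneConfig(n_blocks_x = 5, n_blocks_y = 3, blocks_per_group = 4),
               "divisible")
  expect_error(sceneConfig(sewered_fraction_inside = 1.2), "sewered_fraction")
  expect_error(sceneConfig(pop_noise_sd = -1), "non-negative")
  # too many plants for the region triggers a layout error
  expect_error(generateScene(sceneConfig(n_plants = 500,
                                         region_width = 1000,
                                         region_height = 1000)),
               class = "sewersheds_config_error")
})

test_that("scenes are deterministic field-by-field for a fixed seed", {
  s1 <- generateScene(.smallSceneCfg(seed = 4))
  s2 <- generateScene(.smallSceneCfg(seed = 4))
  expect_identical(featureData(sceneParcels(s1)), featureData(sceneParcels(s2)))
  expect_identical(featureData(scenePlants(s1)), featureData(scenePlants(s2)))
  expect_identical(featureData(sceneCensus(s1, "blocks2010")),
                   featureData(sceneCensus(s2, "blocks2010")))
  expect_identical(s1@truePopulations, s2@truePopulations)
  expect_identical(s1@trueGrowthRates, s2@trueGrowthRates)
  expect_identical(geometry(sceneTrueSewersheds(s1)),
                   geometry(sceneTrueSewersheds(s2)))
})

test_that("random streams are split per layer", {
  base <- generateScene(.smallSceneCfg(seed = 4))
  # changing only the parcel-flag layer leaves capacities and growth alone
  alt <- generateScene(.smallSceneCfg(seed = 4, sewered_fraction_inside = 0.5))
  expect_identical(featureData(scenePlants(base))$capacity,
                   featureData(scenePlants(alt))$capacity)
  expect_identical(base@trueGrowthRates, alt@trueGrowthRates)
})

test_that("true sewersheds are disjoint and contain their plants", {
  sc <- generateScene(.smallSceneCfg(seed = 1, n_plants = 2L))
  sheds <- geometry(sceneTrueSewersheds(sc))
  expect_length(sheds, 2L)
  expect_equal(gpIntersectionArea(sheds[[1]], sheds[[2]]), 0)
  pd <- featureData(scenePlants(sc))
  for (i in 1:2)
    expect_true(gpContains(sheds[[i]], matrix(c(pd$x[i], pd$y[i]), ncol = 2)))
})

test_that("census nesting is exact and population mass is conserved", {
  sc <- smallScene()
  blocks <- sceneCensus(sc, "blocks2010")
  bg <- sceneCensus(sc, "bg2010")
  # mass: blocks and block groups carry the same total
  expect_equal(sum(featureData(blocks)$pop), sum(featureData(bg)$pop),
               tolerance = 1e-9)
  expect_equal(sum(featureData(blocks)$pop), sum(sc@truePopulations),
               tolerance = 1e-9)
  # nesting: each group's geometry measures exactly its member blocks, and
  # the symmetric difference with their union has zero area
  bfd <- featureData(blocks)
  grp <- sub("B", "", bfd$unit_id)
  for (gi in sample(nFeatures(bg), 5)) {
    gg <- geometry(bg)[[gi]]
    # member blocks of group gi in row-major order
    bpg <- sc@config$blocks_per_group
    members <- ((gi - 1) * bpg + 1):(gi * bpg)
    mgeo <- gpoly(unlist(lapply(geometry(blocks)[members],
                                function(g) g$parts), recursive = FALSE))
    inter <- gpIntersectionArea(gg, mgeo)
    symdiff <- gpArea(gg) + gpArea(mgeo) - 2 * inter
    expect_equal(symdiff, 0, tolerance = 1e-9 * gpArea(gg))
  }
})

test_that("sewered parcels lie within exactly one true sewershed", {
  sc <- smallScene()
  fd <- featureData(sceneParcels(sc))
  geoms <- geometry(sceneParcels(sc))
  sheds <- geometry(sceneTrueSewersheds(sc))
  pub <- which(fd$sewer_flag == "public")
  for (i in sample(pub, 40)) {
    vol <- vapply(sheds, function(s) gpIntersectionArea(s, geoms[[i]]), 0)
    inShed <- vol > 1e-9 * gpArea(geoms[[i]])
    expect_equal(sum(inShed), 1L)
    expect_equal(max(vol), gpArea(geoms[[i]]), tolerance = 1e-9)
  }
})

test_that("planted populations follow the capacity line; noise-free r is 1", {
  s0 <- generateScene(.smallSceneCfg(seed = 3, pop_noise_sd = 0,
                                     pop_capacity_slope = 1,
                                     pop_capacity_intercept = 0))
  expect_equal(unname(s0@truePopulations),
               featureData(scenePlants(s0))$capacity, tolerance = 1e-12)
  s0b <- generateScene(.smallSceneCfg(seed = 6, pop_noise_sd = 0,
                                      pop_capacity_slope = 0.8,
                                      pop_capacity_intercept = 2))
  lp <- log10(unname(s0b@truePopulations))
  lc <- log10(featureData(scenePlants(s0b))$capacity)
  expect_equal(stats::cor(lc, lp), 1, tolerance = 1e-12)
  expect_equal(lp, 2 + 0.8 * lc, tolerance = 1e-12)
})

test_that("2018 block groups encode the planted linear growth exactly", {
  sc <- smallScene()
  g10 <- featureData(sceneCensus(sc, "bg2010"))
  g18 <- featureData(sceneCensus(sc, "bg2018"))
  rates <- sc@trueGrowthRates
  shedOf <- g10$true_shed
  for (i in which(!is.na(shedOf) & g10$pop > 0)) {
    pid <- featureData(sceneTrueSewersheds(sc))$plant_id[
      match(shedOf[i], featureData(sceneTrueSewersheds(sc))$shed_id)]
    expect_equal(g18$pop[i], g10$pop[i] * (1 + 8 * rates[[pid]]),
                 tolerance = 1e-12)
  }
})

test_that("scene serialization round-trips layers and attributes", {
  sc <- smallScene()
  dir <- withr::local_tempdir()
  mf <- sceneToDisk(sc, dir)
  expect_gte(nrow(mf), 6L)
  expect_true(all(file.exists(mf$file)))
  # GeoJSON round trip: attributes equal, coordinates to 1e-9
  p <- readVectorLayer(file.path(dir, "parcels.geojson"), "parcels")
  orig <- subsetFeatures(sceneParcels(sc),
                         order(featureData(sceneParcels(sc))$parcel_id))
  expect_identical(featureData(p)[c("parcel_id", "sewer_flag", "district")],
                   featureData(orig)[c("parcel_id", "sewer_flag", "district")])
  i <- 17L
  expect_equal(geometry(p)[[i]]$parts[[1]], geometry(orig)[[i]]$parts[[1]],
               tolerance = 1e-9, ignore_attr = TRUE)
  # cross-format: shapefile parses to the same features
  ps <- readVectorLayer(file.path(dir, "parcels.shp"), "parcels")
  expect_identical(featureData(p)$parcel_id, featureData(ps)$parcel_id)
  dmax <- max(vapply(seq_len(nFeatures(p)), function(k)
    max(abs(geometry(p)[[k]]$parts[[1]] - geometry(ps)[[k]]$parts[[1]])), 0))
  expect_lt(dmax, 1e-9)
})

test_that("writing to an unusable path fails cleanly with no manifest", {
  sc <- smallScene()
  blocker <- withr::local_tempfile()
  writeLines("x", blocker)                    # a file where a dir is needed
  target <- file.path(blocker, "sub")
  expect_error(sceneToDisk(sc, target), class = "sewersheds_io_error")
  expect_false(file.exists(file.path(target, "manifest.json")))
})
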