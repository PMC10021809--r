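# Capacity-correlation QA and urban/rural summaries.

test_that("log10 transform excludes non-positives explicitly", {
  r <- log10Series(c(1, 10, 100))
  expect_equal(r$transformed, c(0, 1, 2))
  expect_length(r$excluded, 0L)
  r2 <- log10Series(c(10, 0, 100))
  expect_equal(r2$transformed, c(1, 2))
  expect_equal(r2$excluded, 2L)
  expect_error(log10Series(c(0, -1)), class = "sewersheds_empty_input_error")
  # distributional: mean of transformed log-normal draws near the log-mean
  set.seed(8)
  draws <- 10^rnorm(1000, mean = 2, sd = 0.5)
  tr <- log10Series(draws)$transformed
  expect_lt(abs(mean(tr) - 2), 3 * 0.5 / sqrt(1000))
})

test_that("pearsonWithP matches the hand covariance formula and limits", {
  x <- 1:10
  expect_equal(pearsonWithP(x, x)$r, 1)
  expect_equal(pearsonWithP(x, -2 * x + 5)$r, -1)
  a <- c(1, 2, 3, 4); b <- c(2, 1, 4, 3)
  res <- pearsonWithP(a, b)
  expect_equal(res$r, handPearson(a, b), tolerance = 1e-12)
  # p from the t distribution with n-2 df
  tstat <- res$r * sqrt((4 - 2) / (1 - res$r^2))
  expect_equal(res$p, 2 * stats::pt(-abs(tstat), df = 2), tolerance = 1e-12)
  expect_error(pearsonWithP(c(1, 1, 1), c(1, 2, 3)),
               class = "sewersheds_degenerate_error")
  expect_error(pearsonWithP(1:2, 1:2), class = "sewersheds_domain_error")
})

test_that("correlations are invariant to affine and positive scaling", {
  set.seed(12)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20, 0, 0.3)
  r0 <- pearsonWithP(x, y)$r
  expect_equal(pearsonWithP(3 * x + 7, y)$r, r0, tolerance = 1e-12)
  xp <- abs(x) + 1; yp <- abs(y) + 1
  rl <- pearsonWithP(log10(xp), log10(yp))$r
  expect_equal(pearsonWithP(log10(5 * xp), log10(yp))$r, rl, tolerance = 1e-12)
})

test_that("noise-free records give r = 1 and a degenerate density stratum", {
  # population equals capacity; area proportional to population at fixed
  # density, so density is constant and its correlation is degenerate
  set.seed(3)
  cap <- 10^rnorm(12, 0, 0.6)
  rec <- data.frame(shed_id = sprintf("S%02d", 1:12),
                    plant_id = sprintf("P%02d", 1:12),
                    capacity = cap, pop = cap * 1000,
                    density = rep(0.001, 12), area = cap * 1e6,
                    method = rep(c("provided", "parcel_cluster"), 6),
                    county_id = "C1", stringsAsFactors = FALSE)
  rep <- qaReport(rec)
  logRows <- rep[rep$scale == "log10", ]
  popRows <- logRows[logRows$pair == "capacity_vs_pop", ]
  areaRows <- logRows[logRows$pair == "capacity_vs_area", ]
  expect_true(all(popRows$estimable))
  expect_equal(popRows$r, rep(1, nrow(popRows)), tolerance = 1e-9)
  expect_equal(areaRows$r, rep(1, nrow(areaRows)), tolerance = 1e-9)
  densRows <- logRows[logRows$pair == "capacity_vs_density", ]
  expect_true(all(!densRows$estimable))    # zero variance, reported as such
  expect_true(all(is.na(densRows$r)))
})

test_that("small strata are reported not-estimable without suppressing others", {
  set.seed(4)
  cap <- 10^rnorm(10, 0, 0.5)
  rec <- data.frame(shed_id = sprintf("S%02d", 1:10),
                    plant_id = sprintf("P%02d", 1:10),
                    capacity = cap, pop = cap * 900 * 10^rnorm(10, 0, 0.1),
                    density = runif(10, 1e-4, 1e-3),
                    area = runif(10, 1e5, 1e7),
                    method = c(rep("parcel_cluster", 8), "village_fallback",
                               "village_fallback"),
                    county_id = "C1", stringsAsFactors = FALSE)
  rep <- qaReport(rec)
  vf <- rep[rep$stratum == "village_fallback", ]
  expect_true(all(!vf$estimable))
  expect_true(all(vf$n < 3))
  pc <- rep[rep$stratum == "parcel_cluster" & rep$scale == "log10" &
            rep$pair == "capacity_vs_pop", ]
  expect_true(pc$estimable)
  expect_error(qaReport(rec[1:2, ]), class = "sewersheds_domain_error")
})

test_that("a stratum can be excluded, mirroring a drop-one-county check", {
  set.seed(6)
  cap <- 10^rnorm(12, 0, 0.5)
  rec <- data.frame(shed_id = sprintf("S%02d", 1:12),
                    plant_id = sprintf("P%02d", 1:12),
                    capacity = cap, pop = cap * 1000 * 10^rnorm(12, 0, 0.2),
                    density = runif(12, 1e-4, 1e-3),
                    area = runif(12, 1e5, 1e7),
                    method = "parcel_cluster",
                    county_id = rep(c("C1", "C2"), each = 6),
                    stringsAsFactors = FALSE)
  full <- qaReport(rec)
  dropped <- qaReport(rec, exclude_stratum = "C2")
  expect_equal(dropped$n[dropped$stratum == "overall"][1], 6)
  expect_false(isTRUE(all.equal(full$r[1], dropped$r[1])))
})

test_that("observed r sits in the Fisher-z interval around the design value", {
  # log10(pop) = a + b log10(cap) + noise with sigma chosen for r = 0.9
  b <- 1; sx <- 0.8
  sigma <- b * sx * sqrt(1 / 0.9^2 - 1)
  n <- 100L
  zlo <- atanh(0.9) - 1.96 / sqrt(n - 3)
  zhi <- atanh(0.9) + 1.96 / sqrt(n - 3)
  cp <- simulateCapacityPopulation(n, a = 4, b = b, sigma = sigma,
                                   log_mean = -0.3, log_sd = sx, seed = 42)
  r <- pearsonWithP(log10(cp$capacity), log10(cp$pop))$r
  expect_gt(atanh(r), zlo)
  expect_lt(atanh(r), zhi)
  # sigma = 0 limit: r exactly 1
  cp0 <- simulateCapacityPopulation(50, a = 4, b = 1, sigma = 0, seed = 9)
  expect_equal(pearsonWithP(log10(cp0$capacity), log10(cp0$pop))$r, 1,
               tolerance = 1e-12)
})

test_that("urban/rural medians match a sort-and-pick oracle", {
  rec <- data.frame(shed_id = sprintf("S%02d", 1:9),
                    plant_id = sprintf("P%02d", 1:9),
                    capacity = c(5, 2, 9, 1, 3, 7, 4, 6, 8),
                    pop = c(10, 20, 90, 15, 25, 35, 40, 50, 60),
                    density = runif(9, 1e-4, 1e-3),
                    area = runif(9, 1e5, 1e6),
                    method = "parcel_cluster",
                    county_id = rep(c("C1", "C2", "C3"), each = 3),
                    stringsAsFactors = FALSE)
  counties <- data.frame(county_id = c("C1", "C2", "C3"),
                         urban = c(TRUE, FALSE, FALSE),
                         pop = c(1000, 1000, 1000))
  s <- urbanRuralSummary(rec, counties)
  # odd-n median by explicit sorting
  urbanPops <- sort(rec$pop[rec$county_id == "C1"])
  expect_equal(s$med_pop[s$class == "urban"], urbanPops[2])
  ruralPops <- sort(rec$pop[rec$county_id != "C1"])
  expect_equal(s$med_pop[s$class == "rural"], mean(ruralPops[3:4]))
  expect_equal(s$n_sheds[s$class == "urban"], 3L)
  # all-urban: rural row flagged empty
  allUrban <- counties; allUrban$urban <- TRUE
  s2 <- urbanRuralSummary(rec, allUrban)
  expect_equal(s2$n_sheds[s2$class == "rural"], 0L)
  expect_equal(s2$flag[s2$class == "rural"], "empty_class")
  expect_error(urbanRuralSummary(rec, counties[1:2, ]),
               class = "sewersheds_reference_error")
})
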