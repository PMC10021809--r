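# Shared fixtures and independent oracles.

# small, fast scene reused across tests (generated once per run)
.smallSceneCfg <- function(seed = 11L, n_plants = 3L, ...) {
  sceneConfig(seed = seed, n_plants = n_plants,
              region_width = 2000, region_height = 2000,
              n_blocks_x = 10L, n_blocks_y = 10L, blocks_per_group = 2L,
              ...)
}

.sceneCache <- new.env(parent = emptyenv())
smallScene <- function() {
  if (is.null(.sceneCache$scene))
    .sceneCache$scene <- generateScene(.smallSceneCfg())
  .sceneCache$scene
}

# Monte-Carlo area-fraction oracle: fraction of a rectangle's area covered
# by geometry g, by uniform point sampling
mcAreaFraction <- function(g, rect, n = 1e5L) {
  px <- stats::runif(n, rect[1L], rect[3L])
  py <- stats::runif(n, rect[2L], rect[4L])
  mean(gpContains(g, cbind(px, py)))
}

# textbook Pearson r from the covariance/variance formula
handPearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# brute-force all-pairs distance components (independent of the sweep)
bruteComponents <- function(geoms, gap) {
  n <- length(geoms)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j) adj[i, j] <- adj[j, i] <- gpDistance(geoms[[i]], geoms[[j]]) <= gap
  }
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && lab[j] > lab[i]) { lab[j] <- lab[i]; changed <- TRUE }
      if (adj[i, j] && lab[i] > lab[j]) { lab[i] <- lab[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# random simple (convex) polygon for geometry fuzzing
randomConvexPoly <- function(cx, cy, rmin = 0.5, rmax = 2, nv = 7L) {
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  r <- stats::runif(nv, rmin, rmax)
  gpoly(cbind(cx + r * cos(ang), cy + r * sin(ang)))
}

# unit-square parcel grid as a ParcelSet
parcelGrid <- function(nx, ny, size = 1, x0 = 0, y0 = 0, flag = "public",
                       prefix = "PC") {
  geoms <- list(); ids <- character(0L)
  k <- 0L
  for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
    k <- k + 1L
    geoms[[k]] <- rectPoly(x0 + (ix - 1) * size, y0 + (iy - 1) * size,
                           x0 + ix * size, y0 + iy * size)
    ids[k] <- sprintf("%s%03d", prefix, k)
  }
  ParcelSet(ids, geoms, sewer_flag = rep(flag, k))
}
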