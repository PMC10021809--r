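# Planar polygon engine.
#
# All geometry in this package lives in one abstract planar Cartesian
# coordinate system (units read as meters); there is no geodesy.  A polygon
# geometry ("gpoly") is a set of simple rings.  Parts of a gpoly built by
# this package's own constructors (grids, Voronoi cells, parcel tiles,
# dissolves) are interior-disjoint, so the region's measure is the sum of
# part measures; geometries whose parts may overlap (e.g. a provided
# boundary merged with parcels) carry disjoint = FALSE and their measure is
# computed exactly by recursive convex-piece inclusion-exclusion.

.AREA_EPS <- 1e-12

#' Polygon geometry constructor
#'
#' Builds a planar polygon geometry from one ring matrix or a list of ring
#' matrices.  Rings are two-column (x, y) matrices without a repeated
#' closing vertex; they are re-oriented counter-clockwise.
#'
#' @param rings a two-column numeric matrix, or a list of such matrices.
#' @param disjoint logical; are the parts known to be interior-disjoint?
#'   When `FALSE`, areas are computed by an exact union-of-convex-pieces
#'   algorithm instead of summing part areas.
#' @return an object of class `gpoly`.
#' @export
gpoly <- function(rings, disjoint = TRUE) {
  if (is.matrix(rings)) rings <- list(rings)
  if (!is.list(rings) || length(rings) == 0L)
    stop("gpoly: need at least one ring")
  rings <- lapply(rings, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "double"
    if (ncol(m) != 2L || nrow(m) < 3L)
      stop("gpoly: each ring must be an n x 2 matrix with n >= 3")
    # drop a duplicated closing vertex if present
    if (isTRUE(all.equal(m[1L, ], m[nrow(m), ], tolerance = 0)))
      m <- m[-nrow(m), , drop = FALSE]
    if (.ringSignedArea(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  })
  structure(list(parts = rings, disjoint = isTRUE(disjoint)), class = "gpoly")
}

#' @export
print.gpoly <- function(x, ...) {
  cat(sprintf("<gpoly: %d part(s), area %.6g>\n", length(x$parts), gpArea(x)))
  invisible(x)
}

is.gpoly <- function(x) inherits(x, "gpoly")

#' Axis-aligned rectangle ring
#' @param xmin,ymin,xmax,ymax rectangle extent.
#' @return a `gpoly` with one rectangular part.
#' @export
rectPoly <- function(xmin, ymin, xmax, ymax) {
  stopifnot(xmax > xmin, ymax > ymin)
  gpoly(rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax)))
}

.ringSignedArea <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(m[, 1L] * m[j, 2L] - m[j, 1L] * m[, 2L]) / 2
}

.ringCentroid <- function(m) {
  n <- nrow(m)
  j <- c(2:n, 1L)
  cr <- m[, 1L] * m[j, 2L] - m[j, 1L] * m[, 2L]
  a <- sum(cr) / 2
  if (abs(a) < .AREA_EPS) return(colMeans(m))
  c(sum((m[, 1L] + m[j, 1L]) * cr), sum((m[, 2L] + m[j, 2L]) * cr)) / (6 * a)
}

.bboxRing <- function(m) c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]), max(m[, 2L]))

#' Bounding box of a geometry
#' @param g a `gpoly`.
#' @return numeric `c(xmin, ymin, xmax, ymax)`.
#' @export
gpBBox <- function(g) {
  bbs <- vapply(g$parts, .bboxRing, numeric(4L))
  c(min(bbs[1L, ]), min(bbs[2L, ]), max(bbs[3L, ]), max(bbs[4L, ]))
}

.bboxOverlap <- function(a, b, pad = 0) {
  a[1L] <= b[3L] + pad && b[1L] <= a[3L] + pad &&
    a[2L] <= b[4L] + pad && b[2L] <= a[4L] + pad
}

#' Exact planar area of a geometry
#'
#' Sum of part areas for interior-disjoint geometries; exact measure of the
#' union of parts otherwise.
#' @param g a `gpoly`.
#' @return area in squared length units.
#' @export
gpArea <- function(g) {
  stopifnot(is.gpoly(g))
  if (g$disjoint || length(g$parts) == 1L)
    sum(vapply(g$parts, function(m) abs(.ringSignedArea(m)), 0))
  else
    gpUnionArea(list(g))
}

#' Area-weighted centroid of a geometry
#' @param g a `gpoly` (parts assumed interior-disjoint).
#' @return numeric `c(x, y)`.
#' @export
gpCentroid <- function(g) {
  a <- vapply(g$parts, function(m) abs(.ringSignedArea(m)), 0)
  cs <- vapply(g$parts, .ringCentroid, numeric(2L))
  if (sum(a) < .AREA_EPS) return(rowMeans(cs))
  as.numeric(cs %*% a / sum(a))
}

# even-odd ray casting, vectorised over points; boundary points count inside
.pointsInRing <- function(px, py, m) {
  n <- nrow(m)
  inside <- logical(length(px))
  x1 <- m[, 1L]; y1 <- m[, 2L]
  x2 <- m[c(2:n, 1L), 1L]; y2 <- m[c(2:n, 1L), 2L]
  for (k in seq_len(n)) {
    crosses <- ((y1[k] > py) != (y2[k] > py))
    if (any(crosses)) {
      xint <- x1[k] + (py[crosses] - y1[k]) / (y2[k] - y1[k]) * (x2[k] - x1[k])
      hit <- px[crosses] < xint
      idx <- which(crosses)[hit]
      inside[idx] <- !inside[idx]
    }
  }
  inside
}

#' Point-in-polygon test
#' @param g a `gpoly`.
#' @param pts an n x 2 matrix of points (or a length-2 vector).
#' @return logical vector, `TRUE` where the point lies in some part.
#' @export
gpContains <- function(g, pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L)
  res <- logical(nrow(pts))
  for (m in g$parts) {
    todo <- which(!res)
    if (length(todo) == 0L) break
    bb <- .bboxRing(m)
    cand <- todo[pts[todo, 1L] >= bb[1L] & pts[todo, 1L] <= bb[3L] &
                 pts[todo, 2L] >= bb[2L] & pts[todo, 2L] <= bb[4L]]
    if (length(cand))
      res[cand] <- .pointsInRing(pts[cand, 1L], pts[cand, 2L], m)
  }
  res
}

.isConvexRing <- function(m, eps = 1e-9) {
  n <- nrow(m)
  if (n == 3L) return(TRUE)
  i0 <- seq_len(n); i1 <- c(2:n, 1L); i2 <- c(3:n, 1L, 2L)
  cr <- (m[i1, 1L] - m[i0, 1L]) * (m[i2, 2L] - m[i1, 2L]) -
        (m[i1, 2L] - m[i0, 2L]) * (m[i2, 1L] - m[i1, 1L])
  scale <- max(abs(cr), 1)
  all(cr >= -eps * scale)
}

# ear clipping for a simple CCW ring; returns list of 3x2 triangle matrices
.triangulateRing <- function(m) {
  if (.ringSignedArea(m) < 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  n <- nrow(m)
  if (n == 3L) return(list(m))
  if (.isConvexRing(m)) {
    return(lapply(2:(n - 1L), function(i) m[c(1L, i, i + 1L), , drop = FALSE]))
  }
  idx <- seq_len(n)
  tris <- vector("list", n - 2L)
  k <- 0L
  guard <- 0L
  scale2 <- max(abs(.ringSignedArea(m)), .AREA_EPS)
  while (length(idx) > 3L) {
    guard <- guard + 1L
    if (guard > 10L * n) stop("triangulation failed: ring may be non-simple")
    nn <- length(idx)
    found <- FALSE
    for (ii in seq_len(nn)) {
      ip <- idx[if (ii == 1L) nn else ii - 1L]
      ic <- idx[ii]
      inx <- idx[if (ii == nn) 1L else ii + 1L]
      a <- m[ip, ]; b <- m[ic, ]; c <- m[inx, ]
      cr <- (b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L])
      if (cr <= 1e-14 * scale2) next          # reflex or degenerate corner
      others <- setdiff(idx, c(ip, ic, inx))
      if (length(others)) {
        tri <- rbind(a, b, c)
        # inclusive test: a vertex on the ear's boundary blocks the ear too
        if (any(.pointsInTriangleIncl(m[others, 1L], m[others, 2L], tri)))
          next
      }
      k <- k + 1L
      tris[[k]] <- rbind(a, b, c)
      idx <- idx[-ii]
      found <- TRUE
      break
    }
    if (!found) {
      # numerically stuck: drop the flattest corner
      nn <- length(idx)
      crs <- vapply(seq_len(nn), function(ii) {
        ip <- idx[if (ii == 1L) nn else ii - 1L]
        ic <- idx[ii]; inx <- idx[if (ii == nn) 1L else ii + 1L]
        abs((m[ic, 1L] - m[ip, 1L]) * (m[inx, 2L] - m[ip, 2L]) -
            (m[ic, 2L] - m[ip, 2L]) * (m[inx, 1L] - m[ip, 1L]))
      }, 0)
      idx <- idx[-which.min(crs)]
    }
  }
  if (length(idx) == 3L) {
    k <- k + 1L
    tris[[k]] <- m[idx, , drop = FALSE]
  }
  tris[seq_len(k)]
}

.pointsInTriangleIncl <- function(px, py, tri) {
  d <- function(ax, ay, bx, by) (bx - ax) * (py - ay) - (by - ay) * (px - ax)
  d1 <- d(tri[1L, 1L], tri[1L, 2L], tri[2L, 1L], tri[2L, 2L])
  d2 <- d(tri[2L, 1L], tri[2L, 2L], tri[3L, 1L], tri[3L, 2L])
  d3 <- d(tri[3L, 1L], tri[3L, 2L], tri[1L, 1L], tri[1L, 2L])
  e <- 1e-9 * (2 * abs(.ringSignedArea(tri)) + 1e-12)
  (d1 > -e & d2 > -e & d3 > -e) | (d1 < e & d2 < e & d3 < e)
}

# convex decomposition of every part
.convexPieces <- function(g) {
  out <- list()
  for (m in g$parts) {
    if (.isConvexRing(m)) out[[length(out) + 1L]] <- m
    else out <- c(out, .triangulateRing(m))
  }
  out
}

# Sutherland-Hodgman: clip any subject ring by one half-plane a*x + b*y <= c
.clipHalfPlane <- function(m, a, b, cc, eps = 1e-12) {
  n <- nrow(m)
  if (n == 0L) return(m)
  v <- a * m[, 1L] + b * m[, 2L] - cc
  scale <- max(abs(v), 1)
  keep <- v <= eps * scale
  if (all(keep)) return(m)
  if (!any(keep)) return(m[0L, , drop = FALSE])
  out <- matrix(0, nrow = 2L * n, ncol = 2L)
  k <- 0L
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    if (keep[i]) { k <- k + 1L; out[k, ] <- m[i, ] }
    if (keep[i] != keep[j]) {
      t <- v[i] / (v[i] - v[j])
      k <- k + 1L
      out[k, ] <- m[i, ] + t * (m[j, ] - m[i, ])
    }
  }
  out[seq_len(k), , drop = FALSE]
}

# clip subject ring by a convex CCW clip ring; exact for convex clip
.clipByConvex <- function(subject, clip) {
  n <- nrow(clip)
  out <- subject
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    # inside of CCW edge (clip[i] -> clip[j]) is the left side:
    # cross(e, p - clip[i]) >= 0  <=>  -ey*x + ex*y <= -ey*cx + ex*cy ... keep left
    ex <- clip[j, 1L] - clip[i, 1L]
    ey <- clip[j, 2L] - clip[i, 2L]
    out <- .clipHalfPlane(out, ey, -ex, ey * clip[i, 1L] - ex * clip[i, 2L])
    if (nrow(out) < 3L) return(out[0L, , drop = FALSE])
  }
  out
}

.convexIntersection <- function(p, q) {
  if (!.bboxOverlap(.bboxRing(p), .bboxRing(q))) return(NULL)
  r <- .clipByConvex(p, q)
  if (nrow(r) < 3L) return(NULL)
  if (abs(.ringSignedArea(r)) < .AREA_EPS) return(NULL)
  if (.ringSignedArea(r) < 0) r <- r[rev(seq_len(nrow(r))), , drop = FALSE]
  r
}

#' Exact intersection area of two geometries
#'
#' Both geometries are decomposed into convex pieces (triangulating
#' non-convex parts); the intersection measure is the sum over piece pairs
#' of convex-convex clip areas.  Exact when each geometry's own parts are
#' interior-disjoint.
#' @param ga,gb `gpoly` geometries.
#' @return intersection area.
#' @export
gpIntersectionArea <- function(ga, gb) {
  stopifnot(is.gpoly(ga), is.gpoly(gb))
  if (!.bboxOverlap(gpBBox(ga), gpBBox(gb))) return(0)
  pa <- .convexPieces(ga)
  pb <- .convexPieces(gb)
  bbb <- lapply(pb, .bboxRing)
  total <- 0
  for (p in pa) {
    bp <- .bboxRing(p)
    for (k in seq_along(pb)) {
      if (!.bboxOverlap(bp, bbb[[k]])) next
      r <- .clipByConvex(p, pb[[k]])
      if (nrow(r) >= 3L) total <- total + abs(.ringSignedArea(r))
    }
  }
  total
}

# measure of the union of convex rings (inclusion-exclusion, recursive)
.measureUnionConvex <- function(ps, depth = 0L) {
  if (length(ps) == 0L) return(0)
  if (depth > 12L) stop("union area: overlap nesting too deep")
  areas <- vapply(ps, function(m) abs(.ringSignedArea(m)), 0)
  ord <- order(-areas)
  ps <- ps[ord]; areas <- areas[ord]
  bbs <- lapply(ps, .bboxRing)
  total <- 0
  for (i in seq_along(ps)) {
    if (areas[i] < .AREA_EPS) next
    inter <- list()
    if (i > 1L) for (j in seq_len(i - 1L)) {
      if (!.bboxOverlap(bbs[[i]], bbs[[j]])) next
      r <- .convexIntersection(ps[[i]], ps[[j]])
      if (!is.null(r)) inter[[length(inter) + 1L]] <- r
    }
    total <- total + areas[i] -
      if (length(inter)) .measureUnionConvex(inter, depth + 1L) else 0
  }
  total
}

#' Exact area of the union of several geometries
#' @param gs a list of `gpoly` geometries (parts may overlap across
#'   geometries; within a geometry marked disjoint they may not).
#' @return the measure of the union.
#' @export
gpUnionArea <- function(gs) {
  if (is.gpoly(gs)) gs <- list(gs)
  pieces <- list()
  for (g in gs) pieces <- c(pieces, .convexPieces(g))
  .measureUnionConvex(pieces)
}

#' Jaccard index of two regions
#' @param ga,gb `gpoly` geometries.
#' @return intersection area over union area (0 when both empty).
#' @export
gpJaccard <- function(ga, gb) {
  i <- gpIntersectionArea(ga, gb)
  u <- gpArea(ga) + gpArea(gb) - i
  if (u <= 0) return(0)
  i / u
}

## ---- distances -------------------------------------------------------------

.ptSegDist2 <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  l2 <- dx * dx + dy * dy
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / pmax(l2, 1e-300)))
  qx <- ax + t * dx; qy <- ay + t * dy
  (px - qx)^2 + (py - qy)^2
}

.segSegDist2 <- function(a, b, c, d) {
  # 0 when the segments properly intersect
  o <- function(p, q, r) sign((q[1L] - p[1L]) * (r[2L] - p[2L]) -
                              (q[2L] - p[2L]) * (r[1L] - p[1L]))
  if (o(a, b, c) != o(a, b, d) && o(c, d, a) != o(c, d, b)) return(0)
  min(.ptSegDist2(c[1L], c[2L], a[1L], a[2L], b[1L], b[2L]),
      .ptSegDist2(d[1L], d[2L], a[1L], a[2L], b[1L], b[2L]),
      .ptSegDist2(a[1L], a[2L], c[1L], c[2L], d[1L], d[2L]),
      .ptSegDist2(b[1L], b[2L], c[1L], c[2L], d[1L], d[2L]))
}

.ringEdges <- function(m) {
  n <- nrow(m)
  list(a = m, b = m[c(2:n, 1L), , drop = FALSE])
}

#' Distance from a geometry to a point
#' @param g a `gpoly`.
#' @param p numeric `c(x, y)`.
#' @return 0 if the point lies inside; otherwise the distance to the boundary.
#' @export
gpPointDistance <- function(g, p) {
  if (gpContains(g, matrix(p, ncol = 2L))) return(0)
  d2 <- Inf
  for (m in g$parts) {
    e <- .ringEdges(m)
    d2 <- min(d2, min(.ptSegDist2(p[1L], p[2L], e$a[, 1L], e$a[, 2L],
                                  e$b[, 1L], e$b[, 2L])))
  }
  sqrt(d2)
}

#' Boundary-to-boundary distance between two geometries
#'
#' Zero when the regions overlap or touch.
#' @param ga,gb `gpoly` geometries.
#' @return separation distance.
#' @export
gpDistance <- function(ga, gb) {
  # overlap: some vertex of one inside the other (crossings give seg dist 0)
  for (m in ga$parts) if (any(gpContains(gb, m))) return(0)
  for (m in gb$parts) if (any(gpContains(ga, m))) return(0)
  d2 <- Inf
  for (ma in ga$parts) {
    ea <- .ringEdges(ma)
    for (mb in gb$parts) {
      bb <- .bboxRing(mb)
      ba <- .bboxRing(ma)
      gap <- sqrt(d2)
      if (is.finite(gap) && !.bboxOverlap(ba, bb, pad = gap)) next
      eb <- .ringEdges(mb)
      for (i in seq_len(nrow(ea$a))) {
        # quick vectorised vertex-to-edges bound first
        d2 <- min(d2, min(.ptSegDist2(ea$a[i, 1L], ea$a[i, 2L],
                                      eb$a[, 1L], eb$a[, 2L],
                                      eb$b[, 1L], eb$b[, 2L])))
      }
      for (i in seq_len(nrow(eb$a))) {
        d2 <- min(d2, min(.ptSegDist2(eb$a[i, 1L], eb$a[i, 2L],
                                      ea$a[, 1L], ea$a[, 2L],
                                      ea$b[, 1L], ea$b[, 2L])))
      }
      if (d2 == 0) return(0)
      # segment-segment crossing check (vertex bounds miss pure crossings)
      for (i in seq_len(nrow(ea$a))) for (j in seq_len(nrow(eb$a))) {
        d2 <- min(d2, .segSegDist2(ea$a[i, ], ea$b[i, ], eb$a[j, ], eb$b[j, ]))
        if (d2 == 0) return(0)
      }
    }
  }
  sqrt(d2)
}

#' Distance from a geometry to a polyline
#' @param g a `gpoly`.
#' @param line an n x 2 matrix of polyline vertices.
#' @return 0 if the line enters the region, else the separation distance.
#' @export
gpLineDistance <- function(g, line) {
  if (any(gpContains(g, line))) return(0)
  d2 <- Inf
  nseg <- nrow(line) - 1L
  for (m in g$parts) {
    e <- .ringEdges(m)
    for (s in seq_len(nseg)) {
      a <- line[s, ]; b <- line[s + 1L, ]
      for (i in seq_len(nrow(e$a))) {
        d2 <- min(d2, .segSegDist2(a, b, e$a[i, ], e$b[i, ]))
        if (d2 == 0) return(0)
      }
    }
  }
  sqrt(d2)
}

#' Representative interior point
#'
#' The area centroid when it falls inside the region, otherwise the centroid
#' of the largest triangle of the triangulation (always interior).
#' @param g a `gpoly`.
#' @return numeric `c(x, y)`.
#' @export
gpInteriorPoint <- function(g) {
  ct <- gpCentroid(g)
  if (gpContains(g, matrix(ct, ncol = 2L))) return(ct)
  pieces <- .convexPieces(g)
  areas <- vapply(pieces, function(m) abs(.ringSignedArea(m)), 0)
  .ringCentroid(pieces[[which.max(areas)]])
}

## ---- Voronoi and convex offsets -------------------------------------------

#' Voronoi cells of point sites clipped to a rectangle
#'
#' Each cell is the intersection of the bounding rectangle with the
#' half-planes closer to its own site than to every other site; cells are
#' convex and partition the rectangle.
#' @param sites an n x 2 matrix of distinct points.
#' @param rect numeric `c(xmin, ymin, xmax, ymax)`.
#' @return a list of convex `gpoly` cells, one per site.
#' @export
voronoiCells <- function(sites, rect) {
  sites <- as.matrix(sites)
  n <- nrow(sites)
  stopifnot(n >= 1L, length(rect) == 4L)
  base <- rbind(c(rect[1L], rect[2L]), c(rect[3L], rect[2L]),
                c(rect[3L], rect[4L]), c(rect[1L], rect[4L]))
  lapply(seq_len(n), function(i) {
    cell <- base
    for (j in seq_len(n)) {
      if (j == i) next
      # keep points with |x - s_i|^2 <= |x - s_j|^2
      a <- 2 * (sites[j, 1L] - sites[i, 1L])
      b <- 2 * (sites[j, 2L] - sites[i, 2L])
      cc <- sum(sites[j, ]^2) - sum(sites[i, ]^2)
      cell <- .clipHalfPlane(cell, a, b, cc)
      if (nrow(cell) < 3L) break
    }
    if (nrow(cell) < 3L) stop("voronoiCells: degenerate cell (coincident sites?)")
    gpoly(cell)
  })
}

#' Inward offset of a convex polygon
#'
#' Clips the polygon by every edge's half-plane moved inward by `d`.
#' @param g a convex single-part `gpoly`.
#' @param d non-negative offset distance.
#' @return a smaller convex `gpoly`, or `NULL` when the offset empties it.
#' @export
shrinkConvex <- function(g, d) {
  stopifnot(is.gpoly(g), length(g$parts) == 1L, d >= 0)
  m <- g$parts[[1L]]
  if (d == 0) return(g)
  if (!.isConvexRing(m)) stop("shrinkConvex: polygon is not convex")
  out <- m
  n <- nrow(m)
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    ex <- m[j, 1L] - m[i, 1L]; ey <- m[j, 2L] - m[i, 2L]
    len <- sqrt(ex^2 + ey^2)
    if (len < 1e-12) next
    # inward normal of a CCW edge is (-ey, ex)/len; move the keep-line in by d
    out <- .clipHalfPlane(out, ey / len, -ex / len,
                          (ey * m[i, 1L] - ex * m[i, 2L]) / len - d)
    if (nrow(out) < 3L) return(NULL)
  }
  if (abs(.ringSignedArea(out)) < .AREA_EPS) return(NULL)
  gpoly(out)
}

## ---- connectivity ----------------------------------------------------------

#' Connected components of geometries under a distance threshold
#'
#' Two geometries are linked when their boundary-to-boundary distance is at
#' most `gap`; components are the transitive closure.  Candidate pairs are
#' pruned by padded bounding boxes via a plane sweep.
#' @param geoms a list of `gpoly` geometries.
#' @param gap non-negative link distance.
#' @return integer vector of component labels (1-based, in order of first
#'   appearance).
#' @export
componentsByDistance <- function(geoms, gap) {
  n <- length(geoms)
  if (n == 0L) return(integer(0L))
  stopifnot(gap >= 0)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  bbs <- t(vapply(geoms, gpBBox, numeric(4L)))
  ord <- order(bbs[, 1L])
  for (oi in seq_len(n)) {
    i <- ord[oi]
    for (oj in seq_len(n)[-seq_len(oi)]) {
      j <- ord[oj]
      if (bbs[j, 1L] > bbs[i, 3L] + gap) break
      if (bbs[j, 2L] > bbs[i, 4L] + gap || bbs[i, 2L] > bbs[j, 4L] + gap) next
      if (find(i) == find(j)) next
      if (gpDistance(geoms[[i]], geoms[[j]]) <= gap) unite(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}
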