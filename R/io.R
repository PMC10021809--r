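# Vector-layer I/O: GeoJSON (RFC 7946 structure, planar coordinates taken
# as given) and ESRI Shapefile (.shp/.shx written directly; .dbf attribute
# tables through foreign::read.dbf/write.dbf), plus CSV attribute tables.
# Attribute column names are <= 10 characters so they survive dBase.

.closeRing <- function(m) rbind(m, m[1L, , drop = FALSE])

.gpolyToCoords <- function(g) {
  lapply(g$parts, function(m) {
    ring <- .closeRing(m)
    lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1L], ring[i, 2L]))
  })
}

.layerTable <- function(layer) {
  if (is(layer, "PlantSet")) {
    d <- featureData(layer)
    list(table = d[setdiff(names(d), c("x", "y"))],
         geoms = lapply(seq_len(nrow(d)), function(i) c(d$x[i], d$y[i])),
         type = "point", id = "plant_id")
  } else if (is(layer, "ParcelSet")) {
    list(table = featureData(layer), geoms = geometry(layer),
         type = "polygon", id = "parcel_id")
  } else if (is(layer, "CensusLayer")) {
    list(table = featureData(layer), geoms = geometry(layer),
         type = "polygon", id = "unit_id")
  } else if (is(layer, "SewershedSet")) {
    list(table = featureData(layer), geoms = geometry(layer),
         type = "polygon", id = "shed_id")
  } else schemaError("unsupported layer class")
}

#' Write a layer as GeoJSON
#'
#' Coordinates are written as stored (one abstract planar system; no
#' longitude/latitude reinterpretation) at full precision.
#'
#' @param layer a `ParcelSet`, `CensusLayer`, `PlantSet` or `SewershedSet`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeGeoJSON <- function(layer, path) {
  lt <- .layerTable(layer)
  d <- lt$table
  feats <- lapply(seq_len(nrow(d)), function(i) {
    props <- as.list(d[i, , drop = FALSE])
    props <- lapply(props, function(v) if (is.na(v)) NULL else v)
    geomobj <- if (lt$type == "point") {
      list(type = "Point", coordinates = as.numeric(lt$geoms[[i]]))
    } else {
      cc <- .gpolyToCoords(lt$geoms[[i]])
      if (length(cc) == 1L) list(type = "Polygon", coordinates = cc)
      else list(type = "MultiPolygon", coordinates = lapply(cc, list))
    }
    list(type = "Feature", properties = props, geometry = geomobj)
  })
  txt <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                          auto_unbox = TRUE, digits = NA, null = "null")
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) ioError(paste("cannot write", path))
  invisible(path)
}

.coordsToRing <- function(cc) {
  m <- do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p)[1:2])))
  m
}

#' Read a GeoJSON layer
#'
#' @param path input file path.
#' @return list with `table` (data.frame of properties) and `geoms` (list
#'   of `gpoly` for areal layers, numeric xy for points) and `type`.
#' @export
readGeoJSON <- function(path) {
  if (!file.exists(path)) ioError(paste("no such file:", path))
  js <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(js$features)) schemaError("not a GeoJSON FeatureCollection")
  feats <- js$features
  props <- lapply(feats, function(f) {
    p <- f$properties
    lapply(p, function(v) if (is.null(v)) NA else v)
  })
  cols <- unique(unlist(lapply(props, names)))
  table <- as.data.frame(
    stats::setNames(lapply(cols, function(cn) {
      vals <- lapply(props, function(p) if (is.null(p[[cn]])) NA else p[[cn]])
      unlist(vals)
    }), cols), stringsAsFactors = FALSE)
  type <- NULL
  geoms <- lapply(feats, function(f) {
    gm <- f$geometry
    switch(gm$type,
      Point = { type <<- "point"; as.numeric(unlist(gm$coordinates)) },
      Polygon = {
        type <<- "polygon"
        gpoly(lapply(gm$coordinates, .coordsToRing))
      },
      MultiPolygon = {
        type <<- "polygon"
        rings <- unlist(lapply(gm$coordinates, function(po)
          lapply(po, .coordsToRing)), recursive = FALSE)
        gpoly(rings)
      },
      schemaError(paste("unsupported geometry type:", gm$type)))
  })
  list(table = table, geoms = geoms, type = type)
}

## ---- ESRI Shapefile --------------------------------------------------------

.shpHeader <- function(con, nbytes, type, bbox) {
  writeBin(9994L, con, size = 4L, endian = "big")
  writeBin(integer(5L), con, size = 4L, endian = "big")
  writeBin(as.integer(nbytes / 2L), con, size = 4L, endian = "big")
  writeBin(1000L, con, size = 4L, endian = "little")
  writeBin(as.integer(type), con, size = 4L, endian = "little")
  writeBin(as.double(c(bbox[1L], bbox[2L], bbox[3L], bbox[4L],
                       0, 0, 0, 0)), con, size = 8L, endian = "little")
}

#' Write geometries as an ESRI Shapefile
#'
#' Writes `.shp` and `.shx` directly (polygon or point records, outer rings
#' clockwise per the format) and the attribute table as `.dbf`.
#'
#' @param layer a layer object.
#' @param path output path; the `.shp`/`.shx`/`.dbf` extensions are added
#'   or replaced.
#' @return the `.shp` path, invisibly.
#' @export
writeShapefile <- function(layer, path) {
  lt <- .layerTable(layer)
  base <- sub("\\.shp$", "", path)
  n <- nrow(lt$table)
  isPoint <- lt$type == "point"
  shpType <- if (isPoint) 1L else 5L

  contents <- vector("list", n)
  for (i in seq_len(n)) {
    if (isPoint) {
      contents[[i]] <- list(xy = as.numeric(lt$geoms[[i]]))
    } else {
      g <- lt$geoms[[i]]
      rings <- lapply(g$parts, function(m) {
        # ESRI outer rings are clockwise
        if (.ringSignedArea(m) > 0) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
        .closeRing(m)
      })
      pts <- do.call(rbind, rings)
      starts <- cumsum(c(0L, vapply(rings, nrow, 0L)))[seq_along(rings)]
      contents[[i]] <- list(bbox = c(min(pts[, 1L]), min(pts[, 2L]),
                                     max(pts[, 1L]), max(pts[, 2L])),
                            parts = as.integer(starts), pts = pts)
    }
  }
  lens <- vapply(contents, function(ct) {
    if (isPoint) 20L
    else 4L + 32L + 8L + 4L * length(ct$parts) + 16L * nrow(ct$pts)
  }, 0L)
  total <- 100L + sum(lens + 8L)
  allbb <- if (isPoint) {
    m <- do.call(rbind, lapply(contents, `[[`, "xy"))
    c(min(m[, 1L]), min(m[, 2L]), max(m[, 1L]), max(m[, 2L]))
  } else {
    m <- do.call(rbind, lapply(contents, `[[`, "bbox"))
    c(min(m[, 1L]), min(m[, 2L]), max(m[, 3L]), max(m[, 4L]))
  }

  con <- tryCatch(file(paste0(base, ".shp"), "wb"), error = function(e) NULL,
                  warning = function(e) NULL)
  if (is.null(con)) ioError(paste("cannot write", paste0(base, ".shp")))
  .shpHeader(con, total, shpType, allbb)
  for (i in seq_len(n)) {
    writeBin(i, con, size = 4L, endian = "big")
    writeBin(as.integer(lens[i] / 2L), con, size = 4L, endian = "big")
    writeBin(shpType, con, size = 4L, endian = "little")
    ct <- contents[[i]]
    if (isPoint) {
      writeBin(as.double(ct$xy), con, size = 8L, endian = "little")
    } else {
      writeBin(as.double(ct$bbox), con, size = 8L, endian = "little")
      writeBin(length(ct$parts), con, size = 4L, endian = "little")
      writeBin(nrow(ct$pts), con, size = 4L, endian = "little")
      writeBin(ct$parts, con, size = 4L, endian = "little")
      writeBin(as.double(t(ct$pts)), con, size = 8L, endian = "little")
    }
  }
  close(con)

  con <- file(paste0(base, ".shx"), "wb")
  .shpHeader(con, 100L + 8L * n, shpType, allbb)
  off <- 50L
  for (i in seq_len(n)) {
    writeBin(off, con, size = 4L, endian = "big")
    writeBin(as.integer(lens[i] / 2L), con, size = 4L, endian = "big")
    off <- off + 4L + as.integer(lens[i] / 2L)
  }
  close(con)

  d <- lt$table
  for (cn in names(d)) if (is.character(d[[cn]])) d[[cn]][is.na(d[[cn]])] <- ""
  foreign::write.dbf(d, paste0(base, ".dbf"))
  invisible(paste0(base, ".shp"))
}

#' Read an ESRI Shapefile
#'
#' @param path the `.shp` path (sibling `.dbf` read when present).
#' @return list with `table`, `geoms`, `type` as in [readGeoJSON()].
#' @export
readShapefile <- function(path) {
  if (!file.exists(path)) ioError(paste("no such file:", path))
  base <- sub("\\.shp$", "", path)
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", 1L, size = 4L, endian = "big")
  if (magic != 9994L) schemaError("not a shapefile")
  invisible(readBin(con, "integer", 6L, size = 4L, endian = "big"))
  invisible(readBin(con, "integer", 1L, size = 4L, endian = "little"))
  shpType <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  invisible(readBin(con, "double", 8L, size = 8L, endian = "little"))
  geoms <- list()
  pos <- 100L
  while (pos < sz) {
    invisible(readBin(con, "integer", 1L, size = 4L, endian = "big"))
    clen <- readBin(con, "integer", 1L, size = 4L, endian = "big")
    rtype <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    if (rtype == 1L) {
      xy <- readBin(con, "double", 2L, size = 8L, endian = "little")
      geoms[[length(geoms) + 1L]] <- xy
    } else if (rtype == 5L) {
      invisible(readBin(con, "double", 4L, size = 8L, endian = "little"))
      nparts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      npts <- readBin(con, "integer", 1L, size = 4L, endian = "little")
      starts <- readBin(con, "integer", nparts, size = 4L, endian = "little")
      coords <- matrix(readBin(con, "double", 2L * npts, size = 8L,
                               endian = "little"),
                       ncol = 2L, byrow = TRUE)
      ends <- c(starts[-1L], npts)
      rings <- lapply(seq_len(nparts), function(k)
        coords[(starts[k] + 1L):ends[k], , drop = FALSE])
      geoms[[length(geoms) + 1L]] <- gpoly(rings)
    } else schemaError(paste("unsupported shapefile record type:", rtype))
    pos <- pos + 8L + 2L * clen
  }
  table <- NULL
  if (file.exists(paste0(base, ".dbf"))) {
    table <- foreign::read.dbf(paste0(base, ".dbf"), as.is = TRUE)
    for (cn in names(table))
      if (is.character(table[[cn]])) {
        table[[cn]] <- trimws(table[[cn]])
        table[[cn]][table[[cn]] == ""] <- NA_character_
      }
  }
  list(table = table, geoms = geoms,
       type = if (shpType == 1L) "point" else "polygon")
}

## ---- schema-validated layer reading ---------------------------------------

.SCHEMAS <- list(
  parcels = list(required = c("parcel_id", "sewer_flag"), id = "parcel_id"),
  census = list(required = c("unit_id", "pop", "vintage", "level"), id = "unit_id"),
  plants = list(required = c("plant_id", "capacity"), id = "plant_id"),
  sewersheds = list(required = c("shed_id", "plant_id", "method"), id = "shed_id"))

#' Read a vector layer with schema validation
#'
#' Format is inferred from the extension (`.geojson`/`.json` or `.shp`).
#' Features are validated against the expected schema, geometries repaired
#' on ingest (ring closure and orientation), and ordered by the schema's id
#' column.
#'
#' @param path input path.
#' @param schema one of `"parcels"`, `"census"`, `"plants"`,
#'   `"sewersheds"`, or NULL for no validation.
#' @return a typed layer object (`ParcelSet`, `CensusLayer`, `PlantSet`,
#'   `SewershedSet`) for known schemas; otherwise the raw
#'   `list(table, geoms, type)`.
#' @export
readVectorLayer <- function(path, schema = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                geojson = , json = readGeoJSON(path),
                shp = readShapefile(path),
                ioError(paste("unsupported format:", ext)))
  if (is.null(schema)) return(raw)
  if (!schema %in% names(.SCHEMAS)) configError(paste("unknown schema:", schema))
  sch <- .SCHEMAS[[schema]]
  miss <- setdiff(sch$required, names(raw$table))
  if (length(miss))
    schemaError(paste0("layer ", path, " missing required attribute(s): ",
                       paste(miss, collapse = ", ")), fields = miss)
  ord <- order(raw$table[[sch$id]])
  tb <- raw$table[ord, , drop = FALSE]
  gs <- raw$geoms[ord]
  opt <- function(cn, default = NA_character_)
    if (cn %in% names(tb)) tb[[cn]] else rep(default, nrow(tb))
  switch(schema,
    parcels = ParcelSet(tb$parcel_id, gs, tb$sewer_flag,
                        district = opt("district"), address = opt("address"),
                        muni_id = opt("muni_id")),
    census = CensusLayer(tb$unit_id, gs, tb$pop, tb$vintage, tb$level),
    plants = {
      xy <- do.call(rbind, gs)
      PlantSet(tb$plant_id, xy[, 1L], xy[, 2L], tb$capacity,
               name = opt("name", NA_character_),
               avg_flow = as.numeric(opt("avg_flow", NA_real_)),
               county_id = opt("county_id"))
    },
    sewersheds = SewershedSet(tb$shed_id, tb$plant_id, gs, tb$method))
}

#' Write a layer's attribute table as CSV
#'
#' UTF-8, header row, '.' decimal point.
#' @param layer a layer object or a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeLayerCSV <- function(layer, path) {
  d <- if (is.data.frame(layer)) layer else .layerTable(layer)$table
  ok <- tryCatch({
    utils::write.csv(d, path, row.names = FALSE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE, warning = function(e) FALSE)
  if (!ok) ioError(paste("cannot write", path))
  invisible(path)
}

#' Write a scene's layers to a directory
#'
#' Each layer is written as GeoJSON and as an ESRI Shapefile, with its
#' attribute table as CSV; the county table, the planted truth (per-plant
#' population and growth rate) and a JSON manifest complete the bundle.
#' Nothing is written unless the directory is writable.
#'
#' @param scene a `SewerScene`.
#' @param directory output directory (created if absent).
#' @return data.frame manifest (`layer`, `file`, `format`, `n`), invisibly
#'   also written as `manifest.json`.
#' @export
sceneToDisk <- function(scene, directory) {
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!ok || file.access(directory, 2L) != 0L)
    ioError(paste("directory not writable:", directory))
  layers <- list(blocks2010 = scene@blocks2010,
                 bg2010 = scene@blockGroups2010,
                 bg2018 = scene@blockGroups2018,
                 parcels = scene@parcels,
                 plants = scene@plants,
                 sheds_true = scene@trueSewersheds)
  rows <- list()
  add <- function(layer, file, format, n)
    rows[[length(rows) + 1L]] <<- data.frame(layer = layer, file = file,
                                             format = format, n = n,
                                             stringsAsFactors = FALSE)
  for (nm in names(layers)) {
    n <- nFeatures(layers[[nm]])
    gj <- file.path(directory, paste0(nm, ".geojson"))
    writeGeoJSON(layers[[nm]], gj); add(nm, gj, "geojson", n)
    sp <- file.path(directory, paste0(nm, ".shp"))
    writeShapefile(layers[[nm]], sp); add(nm, sp, "shapefile", n)
    cs <- file.path(directory, paste0(nm, ".csv"))
    writeLayerCSV(layers[[nm]], cs); add(nm, cs, "csv", n)
  }
  cs <- file.path(directory, "counties.csv")
  writeLayerCSV(scene@counties, cs); add("counties", cs, "csv", nrow(scene@counties))
  truth <- data.frame(plant_id = names(scene@truePopulations),
                      true_pop = as.numeric(scene@truePopulations),
                      growth = as.numeric(scene@trueGrowthRates[names(scene@truePopulations)]),
                      stringsAsFactors = FALSE)
  cs <- file.path(directory, "truth.csv")
  writeLayerCSV(truth, cs); add("truth", cs, "csv", nrow(truth))
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(manifest, file.path(directory, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
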