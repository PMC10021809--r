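# End-to-end pipeline: simulate -> build -> estimate -> qa.
#
# A single seed drives all randomness; two runs with the same config and
# seed reproduce all CSV outputs byte-identically.  All layers must share
# one planar coordinate system; nothing is reprojected.

#' Pipeline configuration
#'
#' Either a scene config (simulate mode) or a set of input layer paths.
#'
#' @param out_dir output directory.
#' @param seed integer seed forwarded to the scene generator.
#' @param scene a [sceneConfig()] to simulate, or NULL to read `paths`.
#' @param paths named list of input paths (`parcels`, `plants`, `blocks`,
#'   `bg2010`, `bg2018`, optionally `counties` CSV); ignored when
#'   simulating.
#' @param builder a [builderConfig()].
#' @param round_outputs round person counts in the estimate table?
#' @param log_level `"info"` or `"quiet"`.
#' @return a named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(out_dir, seed = 1L, scene = sceneConfig(seed = seed),
                           paths = list(), builder = builderConfig(),
                           round_outputs = FALSE,
                           log_level = c("info", "quiet")) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), scene = scene,
                 paths = paths, builder = builder,
                 round_outputs = isTRUE(round_outputs),
                 log_level = match.arg(log_level)),
            class = c("PipelineConfig", "list"))
}

#' Load a pipeline configuration from YAML
#'
#' Recognised keys: `out_dir`, `seed`, `scene` (a mapping of
#' [sceneConfig()] arguments or absent for file mode), `paths`, `builder`
#' (a mapping of [builderConfig()] arguments), `round_outputs`.
#'
#' @param path YAML file.
#' @param seed optional seed overriding the file's.
#' @param out_dir optional output directory overriding the file's.
#' @return a `PipelineConfig`.
#' @export
loadPipelineConfig <- function(path, seed = NULL, out_dir = NULL) {
  if (!file.exists(path)) ioError(paste("no such config file:", path))
  y <- yaml::read_yaml(path)
  seed <- if (!is.null(seed)) as.integer(seed)
          else if (!is.null(y$seed)) as.integer(y$seed) else 1L
  out <- if (!is.null(out_dir)) out_dir
         else if (!is.null(y$out_dir)) y$out_dir
         else configError("config must name an out_dir")
  scene <- if (!is.null(y$scene))
    do.call(sceneConfig, c(list(seed = seed), y$scene[setdiff(names(y$scene), "seed")]))
  else NULL
  builder <- if (!is.null(y$builder)) do.call(builderConfig, y$builder)
             else builderConfig()
  pipelineConfig(out, seed = seed, scene = scene,
                 paths = if (is.null(y$paths)) list() else y$paths,
                 builder = builder,
                 round_outputs = isTRUE(y$round_outputs))
}

.logStage <- function(cfg, stage, msg) {
  if (cfg$log_level == "quiet") return(invisible())
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  lf <- file.path(cfg$out_dir, "pipeline.log")
  if (dir.exists(cfg$out_dir)) cat(line, "\n", file = lf, append = TRUE)
  invisible()
}

#' Run the full pipeline
#'
#' Stages: simulate (when a scene config is present) or load the input
#' layers; build sewersheds (district split when labels are present,
#' otherwise parcel clustering); estimate populations; QA report and
#' urban/rural summary.  Inputs are pre-flight checked before any output
#' is written.
#'
#' @param config a [pipelineConfig()].
#' @return the run manifest, invisibly; artifacts and `run_manifest.json`
#'   are written under `config$out_dir`.
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    configError("config must come from pipelineConfig()")
  cfg <- config
  simulate <- !is.null(cfg$scene)
  if (!simulate) {
    need <- c("parcels", "plants", "blocks", "bg2010", "bg2018")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      configError(paste("missing input path(s):", paste(miss, collapse = ", ")))
    absent <- unlist(cfg$paths[need])[!file.exists(unlist(cfg$paths[need]))]
    if (length(absent))
      configError(paste("input file(s) not found:", paste(absent, collapse = ", ")))
  }
  ok <- dir.exists(cfg$out_dir) ||
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) ioError(paste("cannot create out_dir:", cfg$out_dir))

  stages <- list()
  note <- function(stage, files, n_in, n_out)
    stages[[stage]] <<- list(files = files, n_in = n_in, n_out = n_out,
                             time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))

  counties <- NULL
  if (simulate) {
    .logStage(cfg, "simulate", sprintf("seed %d", cfg$seed))
    scene <- generateScene(cfg$scene)
    sceneDir <- file.path(cfg$out_dir, "scene")
    mf <- sceneToDisk(scene, sceneDir)
    parcels <- scene@parcels
    plants <- scene@plants
    blocks <- scene@blocks2010
    bg2010 <- scene@blockGroups2010
    bg2018 <- scene@blockGroups2018
    counties <- scene@counties
    note("simulate", mf$file, 0L, nFeatures(parcels))
  } else {
    .logStage(cfg, "load", "reading input layers")
    parcels <- readVectorLayer(cfg$paths$parcels, "parcels")
    plants <- readVectorLayer(cfg$paths$plants, "plants")
    blocks <- readVectorLayer(cfg$paths$blocks, "census")
    bg2010 <- readVectorLayer(cfg$paths$bg2010, "census")
    bg2018 <- readVectorLayer(cfg$paths$bg2018, "census")
    if (!is.null(cfg$paths$counties))
      counties <- utils::read.csv(cfg$paths$counties, stringsAsFactors = FALSE)
    note("load", unlist(cfg$paths), 0L, nFeatures(parcels))
  }

  .logStage(cfg, "build", sprintf("%d parcels, %d plants",
                                  nFeatures(parcels), nFeatures(plants)))
  districtMap <- NULL
  fd <- featureData(parcels)
  if (any(!is.na(fd$district))) {
    # route each district to the plant nearest its parcels
    dists <- sort(unique(fd$district[!is.na(fd$district)]))
    pd <- featureData(plants)
    geoms <- geometry(parcels)
    districtMap <- vapply(dists, function(dn) {
      idx <- which(!is.na(fd$district) & fd$district == dn)
      ctr <- colMeans(do.call(rbind, lapply(geoms[idx], gpCentroid)))
      pd$plant_id[order(sqrt((pd$x - ctr[1L])^2 + (pd$y - ctr[2L])^2),
                        pd$plant_id)][1L]
    }, "")
  }
  sheds <- buildSewersheds(parcels, plants, cfg$builder,
                           districtMap = districtMap)
  shedFiles <- c(file.path(cfg$out_dir, "sewersheds.geojson"),
                 file.path(cfg$out_dir, "sewersheds.csv"))
  writeGeoJSON(sheds, shedFiles[1L])
  writeLayerCSV(sheds, shedFiles[2L])
  note("build", shedFiles, nFeatures(parcels), nFeatures(sheds))

  .logStage(cfg, "estimate", sprintf("%d sewersheds", nFeatures(sheds)))
  est <- estimateAll(sheds, blocks, bg2010, bg2018,
                     round_outputs = cfg$round_outputs)
  estFile <- file.path(cfg$out_dir, "estimates.csv")
  writeLayerCSV(est, estFile)
  note("estimate", estFile, nFeatures(sheds), nrow(est))

  .logStage(cfg, "qa", "correlation report")
  rec <- qaRecords(est, plants)
  rep <- qaReport(rec)
  qaFile <- file.path(cfg$out_dir, "qa_report.csv")
  writeLayerCSV(as.data.frame(rep), qaFile)
  qaFiles <- qaFile
  if (!is.null(counties) && !all(is.na(rec$county_id))) {
    urs <- urbanRuralSummary(rec, counties)
    ursFile <- file.path(cfg$out_dir, "urban_rural.csv")
    writeLayerCSV(urs, ursFile)
    qaFiles <- c(qaFiles, ursFile)
  }
  note("qa", qaFiles, nrow(rec), nrow(rep))

  manifest <- list(
    package_version = tryCatch(as.character(utils::packageVersion("sewersheds")),
                               error = function(e) "dev"),
    seed = cfg$seed,
    config = cfg[c("out_dir", "seed", "round_outputs")],
    scene = if (simulate) unclass(cfg$scene) else NULL,
    builder = unclass(cfg$builder),
    stages = stages)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .logStage(cfg, "done", cfg$out_dir)
  invisible(manifest)
}
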