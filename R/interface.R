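# Interface module: run configuration, landscape file I/O, and the
# generate -> simulate -> analyze pipeline with its artifact manifest.
# All file formats are plain text: ASCII grids for rasters, GeoJSON for
# polygons, CSV for points/events/tables, YAML for configuration.

.CONFIG_KEYS <- list(
  landscape = c("source", "preset", "seed", "nRows", "nCols", "cellSize",
                "path"),
  simulation = c("placementSeed", "behaviorSeed", "sampleFraction", "pDeal",
                 "scoutMinKm", "scoutMaxKm", "nTicks", "maxDealFailures",
                 "weights", "startMonth", "startYear"),
  analysis = c("checkpoints", "kdRadiusKm", "sdeNSd", "jenksClasses"),
  output = c("dir", "recordAllTicks"))

#' Default analysis checkpoints
#'
#' The representative mid-season months — January (Jilaal), May (Gu),
#' August (Hagaa), October (Deyr) — of the first and last simulated year,
#' expressed as ticks.
#'
#' @param nTicks run length in months.
#' @param startMonth,startYear calendar anchor of tick 1.
#' @return integer tick vector.
#' @export
defaultCheckpoints <- function(nTicks, startMonth = 1L, startYear = 2008L) {
  lastDate <- tickDate(nTicks, startMonth, startYear)
  years <- unique(c(startYear, lastDate$year))
  ticks <- integer(0)
  for (y in years) for (m in c(1L, 5L, 8L, 10L)) {
    t <- (y - startYear) * 12L + (m - startMonth) + 1L
    if (t >= 1 && t <= nTicks) ticks <- c(ticks, t)
  }
  sort(unique(ticks))
}

#' Load and validate a run configuration
#'
#' YAML with sections `landscape`, `simulation`, `analysis`, `output`.
#' Unknown keys are rejected; defaults are filled for everything omitted
#' (132 ticks, 10% sample, p(deal) 0.5, 15-30 km scouting, mid-season
#' checkpoints of the first and last year).
#'
#' @param path YAML file path.
#' @return validated config list (classed `"pastoralsimRunConfig"`).
#' @export
loadRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  buildRunConfig(raw)
}

#' @rdname loadRunConfig
#' @param config a (possibly partial) configuration list.
#' @export
buildRunConfig <- function(config = list()) {
  for (sec in names(config)) {
    if (!sec %in% names(.CONFIG_KEYS))
      stop("unknown config section: ", sec)
    bad <- setdiff(names(config[[sec]]), .CONFIG_KEYS[[sec]])
    if (length(bad))
      stop(sprintf("unknown key '%s' in section '%s'", bad[1], sec))
  }
  ls <- config$landscape
  if (is.null(ls$source)) ls$source <- "synthetic"
  if (!ls$source %in% c("synthetic", "files"))
    stop("landscape$source must be 'synthetic' or 'files'")
  if (ls$source == "files" && is.null(ls$path))
    stop("landscape$path is required when landscape$source = 'files'")
  if (ls$source == "files" && !dir.exists(ls$path))
    stop("landscape$path does not exist: ", ls$path)
  if (is.null(ls$preset)) ls$preset <- "somaliland"
  if (is.null(ls$seed)) ls$seed <- 1L

  sim <- config$simulation
  defaults <- list(placementSeed = 1L, behaviorSeed = 2L,
                   sampleFraction = 0.1, pDeal = 0.5, scoutMinKm = 15,
                   scoutMaxKm = 30, nTicks = 132L, maxDealFailures = 3L,
                   weights = c(1, 1, 1, -0.25, -1, -0.25),
                   startMonth = 1L, startYear = 2008L)
  for (k in names(defaults)) if (is.null(sim[[k]])) sim[[k]] <- defaults[[k]]
  simCfg <- do.call(simulationConfig, sim)  # validates via the S4 class

  an <- config$analysis
  if (is.null(an$checkpoints))
    an$checkpoints <- defaultCheckpoints(simCfg@nTicks, simCfg@startMonth,
                                         simCfg@startYear)
  an$checkpoints <- as.integer(an$checkpoints)
  if (any(an$checkpoints < 1 | an$checkpoints > simCfg@nTicks))
    stop("analysis$checkpoints must lie within [1, nTicks]")
  if (is.null(an$kdRadiusKm)) an$kdRadiusKm <- 30
  if (is.null(an$sdeNSd)) an$sdeNSd <- 2
  if (is.null(an$jenksClasses)) an$jenksClasses <- 4L

  out <- config$output
  if (is.null(out$dir)) out$dir <- "pastoralsim-run"
  if (is.null(out$recordAllTicks)) out$recordAllTicks <- FALSE

  structure(list(landscape = ls, simulation = sim, simConfig = simCfg,
                 analysis = an, output = out),
            class = "pastoralsimRunConfig")
}

#' Write a run configuration back to YAML
#'
#' Round-trips with [loadRunConfig()]: loading the written file yields an
#' identical configuration.
#'
#' @param config a config from [loadRunConfig()]/[buildRunConfig()].
#' @param path output YAML path.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(list(landscape = config$landscape,
                        simulation = config$simulation,
                        analysis = config$analysis,
                        output = config$output), path)
  invisible(path)
}

# ---- landscape file round-trip ----------------------------------------------

#' Write / read a synthetic landscape to a directory of standard files
#'
#' Rasters as ASCII grids, tessellations as GeoJSON, points and events as
#' CSV, seasons and parameters as CSV/YAML — the same formats the landscape
#' module reads, so generated fixtures exercise the real I/O path.
#'
#' @param landscape a [SyntheticLandscape-class].
#' @param dir output directory (created).
#' @return `writeLandscape` invisibly returns `dir`; `readLandscape`
#'   returns a [SyntheticLandscape-class].
#' @export
writeLandscape <- function(landscape, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ls <- landscape
  writeAsciiGrid(ls@elevation, file.path(dir, "elevation.asc"))
  writeAsciiGrid(ls@surfaceWater, file.path(dir, "surface_water.asc"))
  writeAsciiGrid(ls@privateMask, file.path(dir, "private_mask.asc"))
  writeAsciiGrid(ls@suitabilityMask, file.path(dir, "suitability_mask.asc"))
  writeGeoJSONPolygons(ls@districts, file.path(dir, "districts.geojson"))
  writeGeoJSONPolygons(ls@ethnicTerritories,
                       file.path(dir, "ethnic_territories.geojson"))
  write.csv(ls@settlements, file.path(dir, "settlements.csv"),
            row.names = FALSE)
  write.csv(ls@waterPoints, file.path(dir, "water_points.csv"),
            row.names = FALSE)
  write.csv(ls@conflictEvents, file.path(dir, "conflict_events.csv"),
            row.names = FALSE)
  write.csv(data.frame(district = names(ls@basePopulations),
                       population = as.numeric(ls@basePopulations)),
            file.path(dir, "base_populations.csv"), row.names = FALSE)
  write.csv(data.frame(index = seq_along(ls@seasons),
                       name = vapply(ls@seasons, function(s) s@name, ""),
                       year = vapply(ls@seasons, function(s) s@year, 1L)),
            file.path(dir, "seasons.csv"), row.names = FALSE)
  for (i in seq_along(ls@seasons)) {
    writeAsciiGrid(ls@nir[[i]], file.path(dir, sprintf("nir_s%02d.asc", i)))
    writeAsciiGrid(ls@red[[i]], file.path(dir, sprintf("red_s%02d.asc", i)))
  }
  p <- ls@params
  yaml::write_yaml(list(nRows = p@nRows, nCols = p@nCols,
                        cellSize = p@cellSize, seed = p@seed,
                        startMonth = p@startMonth, startYear = p@startYear,
                        nTicks = p@nTicks, nDistricts = p@nDistricts,
                        nEthnicTerritories = p@nEthnicTerritories),
                   file.path(dir, "landscape.yaml"))
  invisible(dir)
}

#' @rdname writeLandscape
#' @export
readLandscape <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "landscape.yaml"))
  elevation <- readAsciiGrid(file.path(dir, "elevation.asc"))
  template <- rasterGrid(matrix(0, nRows(elevation), nCols(elevation)),
                         elevation@cellSize, elevation@origin)
  districts <- readGeoJSONPolygons(file.path(dir, "districts.geojson"))
  ethnic <- readGeoJSONPolygons(file.path(dir, "ethnic_territories.geojson"))
  seasonsTab <- read.csv(file.path(dir, "seasons.csv"),
                         stringsAsFactors = FALSE)
  seasons <- lapply(seq_len(nrow(seasonsTab)), function(i)
    seasonId(seasonsTab$name[i], seasonsTab$year[i]))
  nir <- lapply(seq_len(nrow(seasonsTab)), function(i)
    readAsciiGrid(file.path(dir, sprintf("nir_s%02d.asc", i))))
  red <- lapply(seq_len(nrow(seasonsTab)), function(i)
    readAsciiGrid(file.path(dir, sprintf("red_s%02d.asc", i))))
  pops <- read.csv(file.path(dir, "base_populations.csv"),
                   stringsAsFactors = FALSE)
  xmax <- nCols(template) * template@cellSize
  ymax <- nRows(template) * template@cellSize
  params <- landscapeParams(nRows = meta$nRows, nCols = meta$nCols,
                            cellSize = meta$cellSize, seed = meta$seed,
                            nDistricts = meta$nDistricts,
                            nEthnicTerritories = meta$nEthnicTerritories,
                            basePopulations = setNames(pops$population,
                                                       pops$district),
                            startMonth = meta$startMonth,
                            startYear = meta$startYear,
                            nTicks = meta$nTicks)
  new("SyntheticLandscape", params = params, template = template,
      districts = districts, districtMatrix = districtRaster(template,
                                                             districts),
      ethnicTerritories = ethnic,
      ethnicMatrix = districtRaster(template, ethnic),
      elevation = elevation,
      surfaceWater = readAsciiGrid(file.path(dir, "surface_water.asc")),
      privateMask = readAsciiGrid(file.path(dir, "private_mask.asc")),
      suitabilityMask = readAsciiGrid(file.path(dir,
                                                "suitability_mask.asc")),
      nir = nir, red = red,
      settlements = read.csv(file.path(dir, "settlements.csv"),
                             stringsAsFactors = FALSE),
      waterPoints = read.csv(file.path(dir, "water_points.csv"),
                             stringsAsFactors = FALSE),
      conflictEvents = read.csv(file.path(dir, "conflict_events.csv"),
                                stringsAsFactors = FALSE),
      basePopulations = setNames(pops$population, pops$district),
      seasons = seasons,
      ethnicBorders = interiorEdges(ethnic, 0, xmax, 0, ymax))
}

# planar coordinates of active agents at a checkpoint
.agentPoints <- function(traj, tick, template) {
  rows <- traj[traj$tick == tick & traj$state == "PASTORALIST", ,
               drop = FALSE]
  cc <- cellCenters(template)
  data.frame(x = cc$x[rows$col], y = cc$y[rows$row])
}

#' Run the full generate -> simulate -> analyze pipeline
#'
#' Builds (or loads) the landscape, synthesizes and places the agent
#' population, runs the monthly decision loop, and writes all checkpoint
#' analyses: per-district counts with Jenks classes, change tables against
#' the first checkpoint, kernel-density statistics, and the standard
#' deviational ellipse table. A manifest records seeds, the conflict
#' normalization constant, and an md5 hash of every artifact.
#'
#' @param config a config from [loadRunConfig()]/[buildRunConfig()].
#' @param landscape optionally a pre-generated
#'   [SyntheticLandscape-class] (overrides the config's landscape section).
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
runPipeline <- function(config, landscape = NULL) {
  if (!inherits(config, "pastoralsimRunConfig"))
    config <- buildRunConfig(config)
  outDir <- config$output$dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  simCfg <- config$simConfig
  stage <- "landscape"
  res <- tryCatch({
    if (is.null(landscape)) {
      landscape <- if (config$landscape$source == "files")
        readLandscape(config$landscape$path)
      else {
        prm <- if (identical(config$landscape$preset, "somaliland")) {
          args <- list(seed = config$landscape$seed)
          for (k in c("nRows", "nCols", "cellSize"))
            if (!is.null(config$landscape[[k]]))
              args[[k]] <- config$landscape[[k]]
          do.call(somalilandPreset, args)
        } else landscapeParams(seed = config$landscape$seed)
        generateLandscape(prm)
      }
    }
    env <- buildSeasonStacks(landscape)

    stage <- "simulation"
    counts <- synthesizePopulation(landscape@basePopulations,
                                   simCfg@sampleFraction)
    eNames <- names(landscape@ethnicTerritories)
    emat <- matrix(eNames[landscape@ethnicMatrix],
                   nrow(landscape@ethnicMatrix))
    agents <- placeAgents(counts, landscape@districtMatrix,
                          landscape@privateMask,
                          landscape@suitabilityMask,
                          simCfg@placementSeed, ethnicityMatrix = emat)
    checkpoints <- config$analysis$checkpoints
    rec <- if (isTRUE(config$output$recordAllTicks)) NULL else checkpoints
    sim <- runSimulation(env$stacks, agents, simCfg, recordTicks = rec)
    traj <- trajectory(sim)
    writeTrajectory(sim, file.path(outDir, "trajectories.csv"))
    write.csv(tickSummary(sim), file.path(outDir, "tick_summary.csv"),
              row.names = FALSE)

    stage <- "analysis"
    dmat <- landscape@districtMatrix
    countTabs <- list()
    sdeRows <- list()
    kdRows <- list()
    for (t in checkpoints) {
      ct <- agentDistrictCounts(traj, t, dmat)
      k <- min(config$analysis$jenksClasses,
               length(unique(ct$counts)))
      cls <- if (k >= 1) jenksClassify(ct$counts, jenksBreaks(ct$counts, k))
             else rep(1L, length(ct$counts))
      tab <- data.frame(district = names(ct$counts),
                        count = as.integer(ct$counts), jenksClass = cls)
      countTabs[[as.character(t)]] <- ct$counts
      write.csv(tab, file.path(outDir, sprintf("counts_tick%03d.csv", t)),
                row.names = FALSE)
      pts <- .agentPoints(traj, t, landscape@template)
      dens <- kernelDensity(pts, config$analysis$kdRadiusKm * 1000,
                            template = landscape@template)
      writeAsciiGrid(dens, file.path(outDir,
                                     sprintf("density_tick%03d.asc", t)))
      kdRows[[as.character(t)]] <- c(tick = t, kdStats(dens))
      sde <- standardDeviationalEllipse(pts, config$analysis$sdeNSd)
      sdeRows[[as.character(t)]] <-
        data.frame(tick = t, areaKm2 = sde@area,
                   centroidX = sde@centroid[1], centroidY = sde@centroid[2],
                   rotationDeg = sde@rotationDeg)
    }
    write.csv(do.call(rbind, lapply(kdRows, function(r)
      as.data.frame(as.list(r)))),
      file.path(outDir, "kd_stats.csv"), row.names = FALSE)
    write.csv(do.call(rbind, sdeRows), file.path(outDir, "sde_table.csv"),
              row.names = FALSE)
    first <- countTabs[[1]]
    changes <- lapply(names(countTabs)[-1], function(t)
      data.frame(district = names(first), tick = as.integer(t),
                 change = as.numeric(countChange(first, countTabs[[t]]))))
    if (length(changes))
      write.csv(do.call(rbind, changes),
                file.path(outDir, "count_changes.csv"), row.names = FALSE)
    list(landscape = landscape, sim = sim, env = env)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  files <- sort(setdiff(list.files(outDir), "manifest.json"))
  manifest <- list(
    package = as.character(utils::packageVersion("pastoralsim")),
    landscapeSeed = config$landscape$seed,
    placementSeed = simCfg@placementSeed,
    behaviorSeed = simCfg@behaviorSeed,
    sampleFraction = simCfg@sampleFraction,
    weights = simCfg@weights,
    conflictGlobalMax = res$env$conflictGlobalMax,
    checkpoints = config$analysis$checkpoints,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(outDir, f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
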