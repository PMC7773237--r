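# Synthetic landscape generator: seeded, parameterized landscapes and event
# streams with the statistical structure of the study inputs — Voronoi
# district and ethnic-territory tessellations, smoothed-noise elevation and
# vegetation fields with wet/dry cycles and drought years, spatio-temporally
# clustered conflict, two-class settlements, clustered water points — so the
# simulator and analyses run with no external geodata. The generator targets
# structure, not statistical realism of any particular dataset.

#' Create a LandscapeParams object
#'
#' Defaults describe a mid-sized test landscape; see [somalilandPreset()]
#' for the full seven-district study-area preset.
#'
#' @param nRows,nCols grid shape.
#' @param cellSize cell edge in meters.
#' @param nDistricts,nEthnicTerritories tessellation sizes.
#' @param nCities,nTowns settlement counts.
#' @param cityRadiusKm,townRadiusKm private-land radii (14 / 4 km).
#' @param targetPrivateFrac add towns until this private share is reached
#'   (NA = keep the exact counts given).
#' @param vegCorrelationKm vegetation spatial correlation length, km.
#' @param wetUplift additive SAVI uplift in wet seasons.
#' @param droughtYears 1-based simulation years with depressed vegetation.
#' @param droughtFactor multiplicative vegetation factor in drought years.
#' @param seasonalNoiseSd sd of the per-season vegetation perturbation.
#' @param conflictLambda per-district per-season Poisson mean (recycled).
#' @param conflictClusterKm spread of within-district conflict clusters.
#' @param nWaterPoints,nWaterClusters,waterClusterKm artificial water
#'   points and their clustering.
#' @param surfaceWaterFrac fraction of cells under surface water.
#' @param bareSoilFrac fraction of cells classed bare soil.
#' @param reliefAmplitudeM,reliefSmoothKm elevation relief shape.
#' @param basePopulations named per-district base populations (length 0 =
#'   drawn from seed).
#' @param seed integer generator seed.
#' @param startMonth,startYear,nTicks simulation window covered.
#' @return a [LandscapeParams-class].
#' @export
landscapeParams <- function(nRows = 60L, nCols = 60L, cellSize = 5000,
                            nDistricts = 7L, nEthnicTerritories = 5L,
                            nCities = 3L, nTowns = 15L,
                            cityRadiusKm = 14, townRadiusKm = 4,
                            targetPrivateFrac = NA_real_,
                            vegCorrelationKm = 30, wetUplift = 0.2,
                            droughtYears = c(3, 4, 9), droughtFactor = 0.5,
                            seasonalNoiseSd = 0.02,
                            conflictLambda = 4, conflictClusterKm = 15,
                            nWaterPoints = 120L, nWaterClusters = 20L,
                            waterClusterKm = 20, surfaceWaterFrac = 0.02,
                            bareSoilFrac = 0.05,
                            reliefAmplitudeM = 600, reliefSmoothKm = 50,
                            basePopulations = numeric(0), seed = 1L,
                            startMonth = 1L, startYear = 2008L,
                            nTicks = 132L) {
  new("LandscapeParams", nRows = as.integer(nRows),
      nCols = as.integer(nCols), cellSize = cellSize,
      nDistricts = as.integer(nDistricts),
      nEthnicTerritories = as.integer(nEthnicTerritories),
      nCities = as.integer(nCities), nTowns = as.integer(nTowns),
      cityRadiusKm = cityRadiusKm, townRadiusKm = townRadiusKm,
      targetPrivateFrac = targetPrivateFrac,
      vegCorrelationKm = vegCorrelationKm, wetUplift = wetUplift,
      droughtYears = droughtYears, droughtFactor = droughtFactor,
      seasonalNoiseSd = seasonalNoiseSd,
      conflictLambda = conflictLambda,
      conflictClusterKm = conflictClusterKm,
      nWaterPoints = as.integer(nWaterPoints),
      nWaterClusters = as.integer(nWaterClusters),
      waterClusterKm = waterClusterKm,
      surfaceWaterFrac = surfaceWaterFrac, bareSoilFrac = bareSoilFrac,
      reliefAmplitudeM = reliefAmplitudeM, reliefSmoothKm = reliefSmoothKm,
      basePopulations = basePopulations, seed = as.integer(seed),
      startMonth = as.integer(startMonth),
      startYear = as.integer(startYear), nTicks = as.integer(nTicks))
}

#' Seven-district study-area preset
#'
#' A reduced-resolution landscape echoing the northern-Somalia setting: a
#' 70 x 70 grid of 10 km cells (490,000 km^2), the seven administrative
#' districts with base populations fixed at ten times their published 10%
#' synthetic-agent counts (totals 225,750, so a 10% sample yields exactly
#' 22,575 agents), 44 seasons spanning 132 monthly ticks from January 2008,
#' drought depression in simulation years 3-4 and 9, an 80/20 public/private
#' land split, and per-district conflict intensities with the strongest
#' activity in Bari.
#'
#' @param seed integer generator seed.
#' @param nRows,nCols,cellSize grid shape overrides (defaults 70 x 70 at
#'   10 km).
#' @return a [LandscapeParams-class].
#' @export
somalilandPreset <- function(seed = 1L, nRows = 70L, nCols = 70L,
                             cellSize = 10000) {
  basePops <- c("Awdal" = 28510, "Woqooyi Galbeed" = 43740,
                "Togdheer" = 24280, "Sool" = 28980, "Sanaag" = 47760,
                "Bari" = 19110, "Nugaal" = 33370)
  lambda <- c("Awdal" = 2, "Woqooyi Galbeed" = 2, "Togdheer" = 5,
              "Sool" = 5, "Sanaag" = 3, "Bari" = 12, "Nugaal" = 1)
  landscapeParams(nRows = nRows, nCols = nCols, cellSize = cellSize,
                  nDistricts = 7L, nEthnicTerritories = 5L,
                  nCities = 8L, nTowns = 40L, targetPrivateFrac = 0.2,
                  conflictLambda = lambda, nWaterPoints = 250L,
                  nWaterClusters = 30L, basePopulations = basePops,
                  seed = seed)
}

setMethod("show", "LandscapeParams", function(object) {
  cat(sprintf("LandscapeParams: %d x %d cells at %.0f km (%s km^2)\n",
              object@nRows, object@nCols, object@cellSize / 1000,
              format(object@nRows * object@nCols *
                       (object@cellSize / 1000)^2, big.mark = ",")))
  cat(sprintf("  %d districts, %d ethnic territories, %d cities + %d towns",
              object@nDistricts, object@nEthnicTerritories, object@nCities,
              object@nTowns))
  cat(sprintf("; seed %d, %d ticks\n", object@seed, object@nTicks))
  invisible(object)
})

# smoothed standard-normal noise field (separable Gaussian blur of white
# noise, edge-replicated); sigma in cells
.smoothNoise <- function(nr, nc, sigma) {
  z <- matrix(rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(z)
  k <- max(1L, ceiling(3 * sigma))
  w <- exp(-0.5 * ((-k:k) / sigma)^2)
  w <- w / sum(w)
  pad <- function(m, k) m[c(rep(1, k), seq_len(nrow(m)), rep(nrow(m), k)), ]
  conv1 <- function(m) {  # along rows (dim 1)
    mp <- pad(m, k)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in -k:k)
      out <- out + w[j + k + 1] * mp[seq_len(nrow(m)) + k + j, , drop = FALSE]
    out
  }
  z <- conv1(z)
  z <- t(conv1(t(z)))
  z / sd(as.vector(z))  # restore unit variance
}

.scale01 <- function(m) {
  r <- range(m)
  if (r[2] == r[1]) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

# sample points with a minimal pairwise separation (dart throwing)
.spacedPoints <- function(n, xmin, xmax, ymin, ymax, minSep) {
  pts <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(pts) < n && tries < 5000L) {
    p <- c(runif(1, xmin, xmax), runif(1, ymin, ymax))
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)) >= minSep) {
      pts <- rbind(pts, p)
    }
    tries <- tries + 1L
  }
  while (nrow(pts) < n)  # give up on separation if the box is too tight
    pts <- rbind(pts, c(runif(1, xmin, xmax), runif(1, ymin, ymax)))
  pts
}

#' SyntheticLandscape: a generated study area
#'
#' Everything [generateLandscape()] fabricates: the template grid, district
#' and ethnic-territory tessellations (polygons plus rasterized index
#' matrices), elevation, per-season NIR/Red reflectance pairs, surface
#' water, settlements and tenure mask, suitability mask, water points,
#' conflict events, base populations, and the ordered season list.
#'
#' @slot params the generating [LandscapeParams-class].
#' @slot template [RasterGrid-class] defining grid geometry.
#' @slot districts,ethnicTerritories named polygon lists.
#' @slot districtMatrix,ethnicMatrix integer index rasters.
#' @slot elevation,surfaceWater,privateMask,suitabilityMask layers.
#' @slot nir,red per-season reflectance [RasterGrid-class] lists.
#' @slot settlements,waterPoints,conflictEvents data.frames.
#' @slot basePopulations named numeric vector.
#' @slot seasons list of [SeasonId-class] in time order.
#' @slot ethnicBorders segment matrix of interior territory borders.
#' @export
setClass("SyntheticLandscape",
  representation(params = "LandscapeParams", template = "RasterGrid",
                 districts = "list", districtMatrix = "matrix",
                 ethnicTerritories = "list", ethnicMatrix = "matrix",
                 elevation = "RasterGrid", surfaceWater = "RasterGrid",
                 privateMask = "RasterGrid", suitabilityMask = "RasterGrid",
                 nir = "list", red = "list", settlements = "data.frame",
                 waterPoints = "data.frame", conflictEvents = "data.frame",
                 basePopulations = "numeric", seasons = "list",
                 ethnicBorders = "matrix"))

setMethod("show", "SyntheticLandscape", function(object) {
  cat(sprintf("SyntheticLandscape: %d x %d cells at %.0f km, %d seasons\n",
              nRows(object@template), nCols(object@template),
              object@template@cellSize / 1000, length(object@seasons)))
  cat(sprintf("  %d districts, %d settlements, %d water points, %d conflict events\n",
              length(object@districts), nrow(object@settlements),
              nrow(object@waterPoints), nrow(object@conflictEvents)))
  cat(sprintf("  private land %.1f%%, suitable %.1f%%\n",
              100 * mean(object@privateMask@values),
              100 * mean(object@suitabilityMask@values)))
  invisible(object)
})

#' Generate a synthetic landscape
#'
#' Fully reproducible from `params@seed`: districts and ethnic territories
#' as bounded Voronoi tessellations of spaced seed points; elevation and
#' vegetation as Gaussian-smoothed noise fields; per-season NIR/Red pairs
#' constructed so the implied SAVI field has the requested correlation
#' length, wet-season uplift and drought-year depression; conflict events
#' drawn from per-district per-season Poisson counts with within-district
#' clustering; settlements, water points and a surface-water mask placed by
#' seeded draws.
#'
#' @param params a [LandscapeParams-class].
#' @return a [SyntheticLandscape-class].
#' @export
generateLandscape <- function(params) {
  validObject(params)
  p <- params
  nr <- p@nRows; nc <- p@nCols; cs <- p@cellSize
  cellKm <- cs / 1000
  template <- rasterGrid(matrix(0, nr, nc), cs, c(0, nr * cs))
  xmax <- nc * cs; ymax <- nr * cs
  seq <- seasonSequence(p@nTicks, p@startMonth, p@startYear)
  seasons <- seq$seasons

  .withSeed(p@seed, {
    # -- tessellations ------------------------------------------------------
    dSep <- 0.35 * sqrt(xmax * ymax / p@nDistricts)
    dSeeds <- .spacedPoints(p@nDistricts, 0, xmax, 0, ymax, dSep)
    dNames <- if (length(p@basePopulations) &&
                  !is.null(names(p@basePopulations)))
      names(p@basePopulations) else paste0("D", seq_len(p@nDistricts))
    rownames(dSeeds) <- dNames
    districts <- voronoiPolygons(dSeeds, 0, xmax, 0, ymax)
    dmat <- districtRaster(template, districts)
    # guard against boundary-tolerance gaps: snap stray cells to nearest seed
    if (any(dmat == 0)) {
      cc <- cellCenters(template)
      miss <- which(dmat == 0)
      for (i in miss) {
        r <- (i - 1L) %% nr + 1L; cl <- (i - 1L) %/% nr + 1L
        d2 <- (dSeeds[, 1] - cc$x[cl])^2 + (dSeeds[, 2] - cc$y[r])^2
        dmat[i] <- which.min(d2)
      }
      attr(dmat, "districts") <- dNames
    }
    eSep <- 0.35 * sqrt(xmax * ymax / p@nEthnicTerritories)
    eSeeds <- .spacedPoints(p@nEthnicTerritories, 0, xmax, 0, ymax, eSep)
    rownames(eSeeds) <- paste0("E", seq_len(p@nEthnicTerritories))
    ethnic <- voronoiPolygons(eSeeds, 0, xmax, 0, ymax)
    emat <- districtRaster(template, ethnic)
    ethnicBorders <- interiorEdges(ethnic, 0, xmax, 0, ymax)

    # -- terrain ------------------------------------------------------------
    elev <- .smoothNoise(nr, nc, p@reliefSmoothKm / cellKm)
    elevation <- rasterGrid(200 + .scale01(elev) * p@reliefAmplitudeM,
                            cs, template@origin)

    # -- vegetation: one base field + seasonal modulation -------------------
    vegBase <- 0.15 + 0.35 * .scale01(.smoothNoise(nr, nc,
                                                   p@vegCorrelationKm / cellKm))
    nirL <- vector("list", length(seasons))
    redL <- vector("list", length(seasons))
    for (i in seq_along(seasons)) {
      s <- seasons[[i]]
      simYear <- s@year - p@startYear + 1L
      base <- vegBase
      if (simYear %in% p@droughtYears) base <- base * p@droughtFactor
      savi <- base + (if (isWet(s)) p@wetUplift else 0)
      if (p@seasonalNoiseSd > 0)
        savi <- savi + p@seasonalNoiseSd *
          .smoothNoise(nr, nc, p@vegCorrelationKm / cellKm)
      savi <- pmin(pmax(savi, 0), 0.95)
      # invert SAVI with L = 0.5: on NIR + Red = 1, SAVI = NIR - Red
      nirL[[i]] <- rasterGrid((1 + savi) / 2, cs, template@origin)
      redL[[i]] <- rasterGrid((1 - savi) / 2, cs, template@origin)
    }

    # -- settlements & tenure ----------------------------------------------
    nCity <- p@nCities; nTown <- p@nTowns
    sx <- runif(nCity + nTown, 0, xmax); sy <- runif(nCity + nTown, 0, ymax)
    settlements <- data.frame(x = sx, y = sy,
                              sizeClass = c(rep("city", nCity),
                                            rep("town", nTown)),
                              stringsAsFactors = FALSE)
    priv <- tenureMask(settlements, template, p@cityRadiusKm, p@townRadiusKm)
    if (is.finite(p@targetPrivateFrac)) {
      guard <- 0L
      extraX <- numeric(0); extraY <- numeric(0)
      while (mean(priv@values) < p@targetPrivateFrac && guard < 20000L) {
        extra <- data.frame(x = runif(1, 0, xmax), y = runif(1, 0, ymax),
                            sizeClass = "town", stringsAsFactors = FALSE)
        # incremental union: only the new town's disk is rasterized
        add <- tenureMask(extra, template, p@cityRadiusKm, p@townRadiusKm)
        priv@values <- pmax(priv@values, add@values)
        extraX <- c(extraX, extra$x); extraY <- c(extraY, extra$y)
        guard <- guard + 1L
      }
      if (length(extraX))
        settlements <- rbind(settlements,
                             data.frame(x = extraX, y = extraY,
                                        sizeClass = "town",
                                        stringsAsFactors = FALSE))
    }

    # -- water and suitability ---------------------------------------------
    wField <- .smoothNoise(nr, nc, 3)
    surfWater <- matrix(0, nr, nc)
    if (p@surfaceWaterFrac > 0)
      surfWater[wField >= quantile(wField, 1 - p@surfaceWaterFrac)] <- 1
    bare <- vegBase <= quantile(vegBase, p@bareSoilFrac)
    suit <- matrix(1, nr, nc)
    suit[surfWater == 1 | bare] <- 0
    # keep every district placeable: re-open the least bare cell if needed
    for (d in seq_len(p@nDistricts)) {
      ok <- dmat == d & suit == 1 & priv@values == 0
      if (!any(ok)) {
        cand <- which(dmat == d & surfWater == 0)
        if (length(cand) == 0) cand <- which(dmat == d)
        best <- cand[which.max(vegBase[cand])]
        suit[best] <- 1
        priv@values[best] <- 0
      }
    }
    nClu <- max(1L, p@nWaterClusters)
    cluX <- runif(nClu, 0, xmax); cluY <- runif(nClu, 0, ymax)
    ci <- sample.int(nClu, p@nWaterPoints, replace = TRUE)
    wpx <- pmin(pmax(cluX[ci] + rnorm(p@nWaterPoints,
                                      sd = p@waterClusterKm * 1000), 1), xmax - 1)
    wpy <- pmin(pmax(cluY[ci] + rnorm(p@nWaterPoints,
                                      sd = p@waterClusterKm * 1000), 1), ymax - 1)
    waterPoints <- data.frame(x = wpx, y = wpy)

    # -- conflict events ----------------------------------------------------
    lambda <- rep_len(p@conflictLambda, p@nDistricts)
    cc <- cellCenters(template)
    ev <- list()
    for (i in seq_along(seasons)) {
      s <- seasons[[i]]
      months <- .seasonMonthsInWindow(s, p@startMonth, p@startYear, p@nTicks)
      if (nrow(months) == 0) next
      for (d in seq_len(p@nDistricts)) {
        nEv <- rpois(1, lambda[d])
        if (nEv == 0) next
        cells <- which(dmat == d)
        ctr <- cells[sample.int(length(cells), 1)]
        ctrX <- cc$x[(ctr - 1L) %/% nr + 1L]
        ctrY <- cc$y[(ctr - 1L) %% nr + 1L]
        ex <- pmin(pmax(ctrX + rnorm(nEv, sd = p@conflictClusterKm * 1000),
                        1), xmax - 1)
        ey <- pmin(pmax(ctrY + rnorm(nEv, sd = p@conflictClusterKm * 1000),
                        1), ymax - 1)
        mi <- sample.int(nrow(months), nEv, replace = TRUE)
        ev[[length(ev) + 1L]] <-
          data.frame(x = ex, y = ey, year = months$year[mi],
                     month = months$month[mi], district = dNames[d],
                     stringsAsFactors = FALSE)
      }
    }
    conflictEvents <- if (length(ev)) do.call(rbind, ev) else
      data.frame(x = numeric(0), y = numeric(0), year = integer(0),
                 month = integer(0), district = character(0))

    # -- base populations ---------------------------------------------------
    basePops <- if (length(p@basePopulations)) p@basePopulations else
      setNames(round(runif(p@nDistricts, 15000, 50000)), dNames)

    new("SyntheticLandscape", params = p, template = template,
        districts = districts, districtMatrix = dmat,
        ethnicTerritories = ethnic, ethnicMatrix = emat,
        elevation = elevation,
        surfaceWater = rasterGrid(surfWater, cs, template@origin),
        privateMask = priv,
        suitabilityMask = rasterGrid(suit, cs, template@origin),
        nir = nirL, red = redL, settlements = settlements,
        waterPoints = waterPoints, conflictEvents = conflictEvents,
        basePopulations = basePops, seasons = seasons,
        ethnicBorders = ethnicBorders)
  })
}

# calendar months of a season that fall inside the simulation window
.seasonMonthsInWindow <- function(season, startMonth, startYear, nTicks) {
  out <- list()
  for (t in seq_len(nTicks)) {
    d <- tickDate(t, startMonth, startYear)
    s <- seasonOfMonth(d$month, d$year)
    if (seasonIndex(s) == seasonIndex(season))
      out[[length(out) + 1L]] <- d
  }
  if (!length(out))
    return(data.frame(month = integer(0), year = integer(0)))
  data.frame(month = vapply(out, `[[`, integer(1), "month"),
             year = vapply(out, `[[`, integer(1), "year"))
}

#' Build per-season environment stacks from a synthetic landscape
#'
#' Runs the landscape-module operations over the generated inputs: seasonal
#' SAVI from the NIR/Red pairs (normalized jointly across the run so wet
#' and drought seasons stay comparable), water layers with the dry-season
#' shutdown, Horn slope, the lag-weighted conflict surface scaled by its
#' global maximum, and the buffered ethnic-border surface.
#'
#' @param landscape a [SyntheticLandscape-class].
#' @param lagWeight conflict carry-over weight (default 0.5).
#' @return list with `stacks` (one [EnvironmentStack-class] per season) and
#'   `conflictGlobalMax` (the logged normalization constant).
#' @export
buildSeasonStacks <- function(landscape, lagWeight = 0.5) {
  ls <- landscape
  template <- ls@template
  seasons <- ls@seasons
  savi <- lapply(seq_along(seasons), function(i)
    computeSavi(ls@nir[[i]], ls@red[[i]]))
  # joint min-max normalization across all seasons
  lo <- min(vapply(savi, function(g) min(g@values, na.rm = TRUE),
                   numeric(1)))
  hi <- max(vapply(savi, function(g) max(g@values, na.rm = TRUE),
                   numeric(1)))
  v1 <- lapply(savi, function(g)
    rasterGrid(if (hi > lo) (g@values - lo) / (hi - lo) else g@values * 0,
               g@cellSize, g@origin))
  v4 <- slopeSurface(ls@elevation)
  v6 <- ethnicBorderSurface(ls@ethnicBorders, template)
  gmax <- conflictGlobalMax(ls@conflictEvents, seasons, template, lagWeight)
  stacks <- vector("list", length(seasons))
  for (i in seq_along(seasons)) {
    s <- seasons[[i]]
    wl <- waterLayers(ls@surfaceWater, ls@waterPoints, s)
    v5 <- conflictSurface(ls@conflictEvents, s, template, lagWeight, gmax)
    stacks[[i]] <- environmentStack(v1[[i]], wl$v2, wl$v3, v4, v5, v6,
                                    ls@privateMask, ls@suitabilityMask, s)
  }
  list(stacks = stacks, conflictGlobalMax = gmax)
}
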