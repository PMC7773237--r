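# S4 classes for the gridded environment, the seasonal calendar, and the
# simulation/analysis results. Nodata cells are represented as NA inside the
# value matrix; all layer algebra requires exact grid alignment.

#' RasterGrid: a single-band gridded field on a planar lattice
#'
#' The common currency of all environment layers: a numeric matrix on a
#' regular, projected (planar, meters) grid. Row 1 is the northernmost row;
#' `origin` is the coordinate of the top-left *corner* of cell (1, 1).
#' Nodata cells are stored as `NA`.
#'
#' @slot values numeric matrix (layer units); `NA` marks nodata.
#' @slot cellSize cell edge length in meters (default 1000 = 1 km).
#' @slot origin numeric(2): planar (x, y) of the top-left corner, meters.
#' @seealso [rasterGrid()], [normalizeLayer()], [isAligned()]
#' @export
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric", origin = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), cellSize = 1000,
            origin = c(0, 0)))

setValidity("RasterGrid", function(object) {
  msgs <- character(0)
  if (!is.numeric(object@values) && !is.logical(object@values))
    msgs <- c(msgs, "values must be a numeric matrix")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msgs <- c(msgs, "cellSize must be a single positive number")
  if (length(object@origin) != 2 || any(!is.finite(object@origin)))
    msgs <- c(msgs, "origin must be two finite planar coordinates")
  if (length(msgs)) msgs else TRUE
})

#' SeasonId: one season of the Somali seasonal calendar
#'
#' Jilaal (long dry, Dec–Mar), Gu (long rains, Apr–Jun), Hagaa (short dry,
#' Jul–Sep), Deyr (short rains, Oct–Nov). December attaches to the Jilaal
#' that spans the year boundary, so Dec 2008 belongs to Jilaal 2009.
#'
#' @slot year calendar year label of the season (see note on December).
#' @slot name one of "Jilaal", "Gu", "Hagaa", "Deyr".
#' @seealso [seasonOf()], [isWet()], [seasonIndex()]
#' @export
setClass("SeasonId", representation(year = "integer", name = "character"))

.SEASON_NAMES <- c("Jilaal", "Gu", "Hagaa", "Deyr")
.WET_SEASONS <- c("Gu", "Deyr")

setValidity("SeasonId", function(object) {
  if (length(object@name) != 1 || !(object@name %in% .SEASON_NAMES))
    return("name must be one of Jilaal, Gu, Hagaa, Deyr")
  if (length(object@year) != 1 || is.na(object@year))
    return("year must be a single integer")
  TRUE
})

#' EnvironmentStack: the six normalized component layers for one season
#'
#' Holds the normalized pull layers (v1 vegetation/SAVI, v2 surface water,
#' v3 artificial water points), the normalized push layers (v4 slope,
#' v5 lag-weighted conflict, v6 ethnic-border proximity) and the two boolean
#' masks (private land, suitability) for one season. All layers must be
#' mutually aligned, all components lie in [0, 1], and v2 is identically
#' zero in dry seasons (surface water is disabled then).
#'
#' @slot v1,v2,v3,v4,v5,v6 [RasterGrid-class] component layers in [0, 1].
#' @slot privateMask [RasterGrid-class] with 0/1 values; 1 = private land.
#' @slot suitabilityMask [RasterGrid-class] with 0/1 values; 1 = suitable.
#' @slot season [SeasonId-class] the season the stack describes.
#' @seealso [environmentStack()], [favorabilitySurface()]
#' @export
setClass("EnvironmentStack",
  representation(v1 = "RasterGrid", v2 = "RasterGrid", v3 = "RasterGrid",
                 v4 = "RasterGrid", v5 = "RasterGrid", v6 = "RasterGrid",
                 privateMask = "RasterGrid", suitabilityMask = "RasterGrid",
                 season = "SeasonId"))

setValidity("EnvironmentStack", function(object) {
  msgs <- character(0)
  layers <- list(object@v1, object@v2, object@v3, object@v4, object@v5,
                 object@v6, object@privateMask, object@suitabilityMask)
  ref <- layers[[1]]
  for (l in layers[-1])
    if (!isAligned(ref, l)) {
      msgs <- c(msgs, "all component layers and masks must be aligned")
      break
    }
  for (i in 1:6) {
    v <- layers[[i]]@values
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE)) {
      msgs <- c(msgs, sprintf("component v%d must lie in [0, 1]", i))
    }
  }
  for (nm in c("privateMask", "suitabilityMask")) {
    v <- slot(object, nm)@values
    if (!all(v %in% c(0, 1) | is.na(v)))
      msgs <- c(msgs, sprintf("%s must be binary 0/1", nm))
  }
  if (!isWet(object@season) && any(object@v2@values != 0, na.rm = TRUE))
    msgs <- c(msgs, "v2 (surface water) must be all zero in dry seasons")
  if (length(msgs)) msgs else TRUE
})

#' SdeResult: a k-standard-deviation deviational ellipse
#'
#' Summary of a planar point set: centroid, semi-axes at the requested
#' standard-deviation multiple, rotation of the major axis measured
#' clockwise from north in [0, 180), and ellipse area in km^2.
#'
#' @slot area ellipse area in km^2 (= pi * a * b / 1e6).
#' @slot centroid numeric(2) mean center (x, y), meters.
#' @slot rotationDeg major-axis bearing, degrees clockwise from north,
#'   reduced to [0, 180).
#' @slot semiAxes numeric(2) (a, b) semi-axis lengths in meters, a >= b.
#' @slot nSd the standard-deviation multiple applied (default 2).
#' @slot n number of points summarized.
#' @seealso [standardDeviationalEllipse()], [sdeSummary()]
#' @export
setClass("SdeResult",
  representation(area = "numeric", centroid = "numeric",
                 rotationDeg = "numeric", semiAxes = "numeric",
                 nSd = "numeric", n = "integer"))

setValidity("SdeResult", function(object) {
  msgs <- character(0)
  a <- object@semiAxes[1]; b <- object@semiAxes[2]
  if (length(object@semiAxes) != 2 || a < b - 1e-9 || b < -1e-9)
    msgs <- c(msgs, "semiAxes must satisfy a >= b >= 0")
  if (abs(object@area - pi * a * b / 1e6) > 1e-6 * max(1, object@area))
    msgs <- c(msgs, "area must equal pi*a*b/1e6 km^2")
  if (object@rotationDeg < 0 || object@rotationDeg >= 180)
    msgs <- c(msgs, "rotationDeg must lie in [0, 180)")
  if (length(msgs)) msgs else TRUE
})

#' SimulationConfig: parameters of the monthly decision loop
#'
#' @slot placementSeed integer seed governing agent start positions only.
#' @slot behaviorSeed integer seed governing scouting radii and deal draws.
#' @slot sampleFraction fraction of the base population synthesized (0, 1].
#' @slot pDeal probability that a land-sharing negotiation succeeds.
#' @slot scoutMinKm,scoutMaxKm bounds of the uniform scouting radius (km).
#' @slot nTicks number of monthly ticks (default 132 = 11 years).
#' @slot maxDealFailures failed deals per season that trigger drop-out (3).
#' @slot weights numeric(6): coefficients of the additive favorability score,
#'   default (+1, +1, +1, -0.25, -1, -0.25) for (v1..v6).
#' @slot startMonth,startYear calendar anchor of tick 1 (default Jan 2008).
#' @seealso [simulationConfig()], [runSimulation()]
#' @export
setClass("SimulationConfig",
  representation(placementSeed = "integer", behaviorSeed = "integer",
                 sampleFraction = "numeric", pDeal = "numeric",
                 scoutMinKm = "numeric", scoutMaxKm = "numeric",
                 nTicks = "integer", maxDealFailures = "integer",
                 weights = "numeric", startMonth = "integer",
                 startYear = "integer"))

setValidity("SimulationConfig", function(object) {
  msgs <- character(0)
  if (object@sampleFraction <= 0 || object@sampleFraction > 1)
    msgs <- c(msgs, "sampleFraction must lie in (0, 1]")
  if (object@pDeal < 0 || object@pDeal > 1)
    msgs <- c(msgs, "pDeal must lie in [0, 1]")
  if (object@scoutMinKm > object@scoutMaxKm)
    msgs <- c(msgs, "scoutMinKm must not exceed scoutMaxKm")
  if (object@scoutMinKm < 0)
    msgs <- c(msgs, "scouting radii must be non-negative")
  if (object@nTicks < 1) msgs <- c(msgs, "nTicks must be >= 1")
  if (object@maxDealFailures < 1)
    msgs <- c(msgs, "maxDealFailures must be >= 1")
  if (length(object@weights) != 6)
    msgs <- c(msgs, "weights must have length 6 (v1..v6)")
  if (object@startMonth < 1 || object@startMonth > 12)
    msgs <- c(msgs, "startMonth must be in 1..12")
  if (length(msgs)) msgs else TRUE
})

#' LandscapeParams: parameters of the synthetic landscape generator
#'
#' Describes the statistical structure of a generated study area: grid shape
#' and resolution, district and ethnic-territory tessellations, seasonal
#' vegetation dynamics (spatial correlation, wet-season uplift, drought
#' years), clustered conflict, settlements of two size classes, water
#' layers, and per-district base populations. All randomness flows from
#' `seed`.
#'
#' @slot nRows,nCols grid shape.
#' @slot cellSize cell edge in meters.
#' @slot nDistricts,nEthnicTerritories tessellation sizes.
#' @slot nCities,nTowns settlement counts (private-land anchors).
#' @slot cityRadiusKm,townRadiusKm private-land radii (default 14 / 4 km).
#' @slot targetPrivateFrac if finite, extra towns are added until the private
#'   share of the grid reaches this fraction (NA = off).
#' @slot vegCorrelationKm spatial correlation length of vegetation fields.
#' @slot wetUplift additive SAVI uplift applied in wet seasons.
#' @slot droughtYears simulation years (1-based) with depressed vegetation.
#' @slot droughtFactor multiplicative vegetation factor in drought years.
#' @slot seasonalNoiseSd sd of the small per-season vegetation perturbation.
#' @slot conflictLambda per-district per-season Poisson mean of conflict
#'   event counts (scalar recycled, or one value per district).
#' @slot conflictClusterKm within-district spread of conflict clusters.
#' @slot nWaterPoints,nWaterClusters,waterClusterKm artificial water points.
#' @slot surfaceWaterFrac fraction of cells covered by surface water bodies.
#' @slot bareSoilFrac fraction of cells classed bare soil (unsuitable).
#' @slot reliefAmplitudeM,reliefSmoothKm elevation field shape.
#' @slot basePopulations per-district base populations (named numeric);
#'   length 0 = draw from seed.
#' @slot seed integer generator seed.
#' @slot startMonth,startYear,nTicks simulation window the landscape covers.
#' @seealso [landscapeParams()], [somalilandPreset()], [generateLandscape()]
#' @export
setClass("LandscapeParams",
  representation(nRows = "integer", nCols = "integer", cellSize = "numeric",
                 nDistricts = "integer", nEthnicTerritories = "integer",
                 nCities = "integer", nTowns = "integer",
                 cityRadiusKm = "numeric", townRadiusKm = "numeric",
                 targetPrivateFrac = "numeric",
                 vegCorrelationKm = "numeric", wetUplift = "numeric",
                 droughtYears = "numeric", droughtFactor = "numeric",
                 seasonalNoiseSd = "numeric",
                 conflictLambda = "numeric", conflictClusterKm = "numeric",
                 nWaterPoints = "integer", nWaterClusters = "integer",
                 waterClusterKm = "numeric", surfaceWaterFrac = "numeric",
                 bareSoilFrac = "numeric",
                 reliefAmplitudeM = "numeric", reliefSmoothKm = "numeric",
                 basePopulations = "numeric", seed = "integer",
                 startMonth = "integer", startYear = "integer",
                 nTicks = "integer"))

setValidity("LandscapeParams", function(object) {
  msgs <- character(0)
  if (object@nRows < 5 || object@nCols < 5)
    msgs <- c(msgs, "grid must be at least 5 x 5")
  if (object@nDistricts < 1) msgs <- c(msgs, "nDistricts must be >= 1")
  if (object@nRows * object@nCols < 4 * object@nDistricts)
    msgs <- c(msgs, "grid too small for the requested district tessellation")
  for (nm in c("surfaceWaterFrac", "bareSoilFrac"))
    if (slot(object, nm) < 0 || slot(object, nm) > 1)
      msgs <- c(msgs, sprintf("%s must lie in [0, 1]", nm))
  if (any(object@conflictLambda < 0))
    msgs <- c(msgs, "conflictLambda must be non-negative")
  if (length(object@basePopulations) &&
      length(object@basePopulations) != object@nDistricts)
    msgs <- c(msgs, "basePopulations must have one entry per district")
  if (any(object@basePopulations < 0))
    msgs <- c(msgs, "basePopulations must be non-negative")
  if (length(msgs)) msgs else TRUE
})
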