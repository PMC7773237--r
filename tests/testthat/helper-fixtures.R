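# Shared fixtures, all built in code.

# small grid with prescribed values (1 km cells, origin at (0, nr km))
smallGrid <- function(values, cellSize = 1000) {
  m <- as.matrix(values)
  rasterGrid(m, cellSize, c(0, nrow(m) * cellSize))
}

# a flat, all-public, all-suitable environment stack for one season
flatStack <- function(nr = 5, nc = 5, season = seasonId("Jilaal", 2008),
                      cellSize = 1000, v1 = 0.5) {
  z <- function(x) rasterGrid(matrix(x, nr, nc), cellSize,
                              c(0, nr * cellSize))
  environmentStack(z(v1), z(0), z(0), z(0), z(0), z(0),
                   privateMask = z(0), suitabilityMask = z(1),
                   season = season)
}

# the flat stacks needed to cover an nTicks run starting Jan 2008
flatStackSeries <- function(nTicks, nr = 5, nc = 5, cellSize = 1000,
                            v1 = 0.5) {
  sq <- seasonSequence(nTicks)
  lapply(sq$seasons, function(s)
    flatStack(nr, nc, s, cellSize, v1))
}

# two unit-square districts side by side, in meters
twoSquareDistricts <- function(w = 1000) {
  list(A = cbind(c(0, w, w, 0), c(0, 0, w, w)),
       B = cbind(c(w, 2 * w, 2 * w, w), c(0, 0, w, w)))
}

# tiny synthetic landscape parameters for fast interface tests
tinyParams <- function(seed = 1L, nTicks = 12L) {
  landscapeParams(nRows = 20L, nCols = 20L, cellSize = 5000,
                  nDistricts = 3L, nEthnicTerritories = 2L,
                  nCities = 1L, nTowns = 4L, nWaterPoints = 20L,
                  nWaterClusters = 4L, conflictLambda = 2,
                  basePopulations = c(A = 900, B = 600, C = 500),
                  seed = seed, nTicks = nTicks)
}

refPath <- function(file) system.file("extdata", file,
                                      package = "pastoralsim")
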