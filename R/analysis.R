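# Spatial-analysis module: per-district counts and change tables, Jenks
# natural-breaks classification, quadratic-kernel density surfaces, and
# standard deviational ellipses over agent point patterns. All distances
# are planar (projected meters).

#' Per-district point counts
#'
#' Each point is assigned to the unique containing district; points lying
#' exactly on a shared boundary go to the first district in list order
#' (deterministic containment rule). Points outside every district are
#' counted separately and excluded from the table.
#'
#' @param points data.frame/matrix with `x`, `y` planar meters.
#' @param districts named list of district polygon vertex matrices.
#' @return list with `counts` (named integer vector) and `outside`
#'   (number of excluded points).
#' @export
districtCounts <- function(points, districts) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  assigned <- integer(n)  # 0 = outside
  for (i in seq_along(districts)) {
    free <- assigned == 0L
    if (!any(free)) break
    inside <- pointInPolygon(pts$x[free], pts$y[free], districts[[i]])
    assigned[free][inside] <- i
  }
  counts <- vapply(seq_along(districts), function(i) sum(assigned == i),
                   integer(1))
  names(counts) <- names(districts)
  list(counts = counts, outside = sum(assigned == 0L))
}

#' Per-district counts of active agents at one tick
#'
#' Fast grid-based variant used on simulation output: agents sit on cell
#' centers, so district membership is read off a rasterized tessellation.
#'
#' @param traj trajectory data.frame (see [runSimulation()]).
#' @param tick the tick to tabulate.
#' @param dmat integer district raster from [districtRaster()].
#' @return list with `counts` (named) and `outside`.
#' @export
agentDistrictCounts <- function(traj, tick, dmat) {
  rows <- traj[traj$tick == tick & traj$state == "PASTORALIST", ,
               drop = FALSE]
  dnames <- attr(dmat, "districts")
  d <- dmat[cbind(rows$row, rows$col)]
  counts <- vapply(seq_along(dnames), function(i) sum(d == i), integer(1))
  names(counts) <- dnames
  list(counts = counts, outside = sum(d == 0L))
}

#' Change table between two count tables
#'
#' Signed per-district differences, end minus start.
#'
#' @param before,after named numeric vectors over identical district keys.
#' @return named numeric vector of `after - before`.
#' @export
countChange <- function(before, after) {
  if (!setequal(names(before), names(after)))
    stop("count tables have mismatched district keys")
  after[names(before)] - before
}

#' Most/least populated districts and their difference
#'
#' @param counts named numeric vector.
#' @return list with `maxDistrict`, `minDistrict`, `span` (max - min).
#' @export
rangeSpan <- function(counts) {
  if (length(counts) == 0) stop("empty counts table")
  list(maxDistrict = names(counts)[which.max(counts)],
       minDistrict = names(counts)[which.min(counts)],
       span = as.numeric(max(counts) - min(counts)))
}

#' Jenks natural breaks (exact Fisher-Jenks optimization)
#'
#' Dynamic program minimizing the total within-class sum of squared
#' deviations over all partitions of the sorted values into `k` contiguous
#' classes. Returns the `k - 1` break points as the largest value of each
#' class but the last.
#'
#' @param values numeric vector.
#' @param k number of classes, `1 <= k <=` number of distinct values.
#' @return numeric vector of `k - 1` breaks (empty for `k = 1`).
#' @examples
#' jenksBreaks(c(1, 2, 3, 10, 11, 12), 2)  # 3
#' @export
jenksBreaks <- function(values, k) {
  x <- sort(as.numeric(values))
  n <- length(x)
  if (k < 1) stop("k must be >= 1")
  if (k > length(unique(x)))
    stop("k must not exceed the number of distinct values")
  if (k == 1) return(numeric(0))
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  ssd <- function(i, j) {  # within-class SSD of x[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[m, j]: minimal cost of splitting x[1..j] into m classes
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)  # last class of optimum starts at B[m, j]
  for (j in 1:n) { D[1, j] <- ssd(1, j); B[1, j] <- 1L }
  for (m in 2:k) {
    for (j in m:n) {
      for (s in m:j) {  # last class is x[s..j]
        cost <- D[m - 1, s - 1] + ssd(s, j)
        if (cost < D[m, j] - 1e-12) { D[m, j] <- cost; B[m, j] <- s }
      }
    }
  }
  # backtrack class boundaries
  breaks <- numeric(k - 1)
  j <- n
  for (m in k:2) {
    s <- B[m, j]
    breaks[m - 1] <- x[s - 1]
    j <- s - 1L
  }
  breaks
}

#' Classify values by break points
#'
#' @param values numeric vector.
#' @param breaks ascending break values (class upper bounds, inclusive).
#' @return integer class indices in `1..(length(breaks) + 1)`.
#' @export
jenksClassify <- function(values, breaks) {
  findInterval(values, breaks, left.open = TRUE) + 1L
}

#' Quadratic-kernel density surface
#'
#' density(c) = (1 / radius^2) * sum over points i with dist_i < radius of
#' (3 / pi) * pop_i * (1 - (dist_i / radius)^2)^2, evaluated at cell
#' centers: the quadratic (Epanechnikov-family) kernel with highest weight
#' at the point location, tapering to zero at the search radius. The 3/pi
#' constant makes each point's surface integrate to its `pop` weight.
#' Values are reported per km^2.
#'
#' @param points data.frame with `x`, `y` (meters) and optional `pop`
#'   weights (default 1 per point).
#' @param radius search radius in meters.
#' @param template optional [RasterGrid-class] fixing the output grid;
#'   otherwise a grid of `cellSize` covering the points plus the radius.
#' @param cellSize output resolution in meters (default 1000 = 1 km) when
#'   no template is given.
#' @return a [RasterGrid-class] of densities (agents per km^2).
#' @export
kernelDensity <- function(points, radius, template = NULL,
                          cellSize = 1000) {
  if (radius <= 0) stop("radius must be positive")
  pts <- as.data.frame(points)
  if (is.null(pts$pop)) pts$pop <- rep(1, nrow(pts))
  if (any(pts$pop < 0)) stop("pop weights must be non-negative")
  if (is.null(template)) {
    if (nrow(pts) == 0) stop("empty point set needs an explicit template")
    xmin <- min(pts$x) - radius; xmax <- max(pts$x) + radius
    ymin <- min(pts$y) - radius; ymax <- max(pts$y) + radius
    nc <- max(1L, ceiling((xmax - xmin) / cellSize))
    nr <- max(1L, ceiling((ymax - ymin) / cellSize))
    template <- rasterGrid(matrix(0, nr, nc), cellSize, c(xmin, ymax))
  }
  nr <- nRows(template); nc <- nCols(template); cs <- template@cellSize
  dens <- matrix(0, nr, nc)
  cc <- cellCenters(template)
  for (i in seq_len(nrow(pts))) {
    ic <- which(abs(cc$x - pts$x[i]) < radius)
    ir <- which(abs(cc$y - pts$y[i]) < radius)
    if (!length(ic) || !length(ir)) next
    dx <- cc$x[ic] - pts$x[i]
    dy <- cc$y[ir] - pts$y[i]
    d2 <- outer(dy^2, dx^2, "+")
    w <- 1 - d2 / radius^2
    w[w < 0] <- 0
    dens[ir, ic] <- dens[ir, ic] + (3 / pi) * pts$pop[i] * w^2
  }
  dens <- dens / radius^2 * 1e6  # per m^2 -> per km^2
  rasterGrid(dens, cs, template@origin)
}

#' Summary statistics of a density surface
#'
#' Minimum, maximum, mean and standard deviation over all non-nodata cells.
#' The sd uses the population (1/N) convention, matching how raster map
#' statistics are conventionally reported.
#'
#' @param density a [RasterGrid-class].
#' @return named numeric vector `(min, max, mean, sd)`.
#' @export
kdStats <- function(density) {
  v <- density@values[!is.na(density@values)]
  if (length(v) == 0) stop("empty raster")
  m <- mean(v)
  c(min = min(v), max = max(v), mean = m,
    sd = sqrt(mean((v - m)^2)))
}

#' Standard deviational ellipse of a point set
#'
#' Centroid = mean center; covariance matrix with the 1/n divisor;
#' semi-axes = `nSd` times the square roots of its eigenvalues; rotation =
#' bearing of the major axis measured clockwise from north, reduced to
#' [0, 180). Area = pi * a * b, reported in km^2. At the conventional
#' `nSd = 2` the ellipse covers most of the point mass (about 86% for an
#' isotropic bivariate normal, by the Rayleigh closed form).
#'
#' @param points data.frame/matrix with `x`, `y` planar meters.
#' @param nSd standard-deviation multiple (default 2).
#' @return an [SdeResult-class].
#' @export
standardDeviationalEllipse <- function(points, nSd = 2) {
  pts <- as.data.frame(points)
  n <- nrow(pts)
  if (n < 2) stop("at least 2 points are required")
  xb <- mean(pts$x); yb <- mean(pts$y)
  xt <- pts$x - xb; yt <- pts$y - yb
  C <- matrix(c(mean(xt^2), mean(xt * yt),
                mean(xt * yt), mean(yt^2)), 2, 2)
  e <- eigen(C, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  a <- nSd * sqrt(ev[1]); b <- nSd * sqrt(ev[2])
  if (b < 1e-9 * max(a, 1))
    warning("collinear points: degenerate ellipse (area 0)")
  v <- e$vectors[, 1]  # major axis direction
  rot <- atan2(v[1], v[2]) * 180 / pi  # clockwise from north
  rot <- rot %% 180
  new("SdeResult", area = pi * a * b / 1e6, centroid = c(xb, yb),
      rotationDeg = rot, semiAxes = c(a, b), nSd = nSd, n = n)
}

setMethod("show", "SdeResult", function(object) {
  cat(sprintf("SdeResult (%g SD, n = %d):\n", object@nSd, object@n))
  cat(sprintf("  area %.0f km^2; centroid (%.1f, %.1f) m; rotation %.2f deg\n",
              object@area, object@centroid[1], object@centroid[2],
              object@rotationDeg))
  invisible(object)
})

#' Summaries over a sequence of deviational ellipses
#'
#' @param results list of [SdeResult-class], or a numeric vector of areas
#'   (km^2) when only areal summaries are wanted.
#' @return list with `meanArea`, `areaSpan` (max - min) and
#'   `centroidDrift` (meters between the first and last centroid; `NA`
#'   when only areas were given).
#' @examples
#' sdeSummary(c(578675, 599409, 600534, 600450))
#' @export
sdeSummary <- function(results) {
  if (is.numeric(results)) {
    areas <- results
    drift <- NA_real_
  } else {
    if (length(results) == 0) stop("empty result list")
    areas <- vapply(results, function(r) r@area, numeric(1))
    c1 <- results[[1]]@centroid
    c2 <- results[[length(results)]]@centroid
    drift <- sqrt(sum((c2 - c1)^2))
  }
  if (length(areas) == 0) stop("empty result list")
  list(meanArea = as.numeric(mean(areas)),
       areaSpan = as.numeric(max(areas) - min(areas)),
       centroidDrift = drift)
}
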