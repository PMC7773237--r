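# Landscape module: builds the per-season favorability surface components
# from raw geodata. All layers are min-max normalized to [0, 1] and combined
# by the additive score
#   score = v1 + v2 + v3 - 0.25 * v4 - v5 - 0.25 * v6
# with v1 vegetation (SAVI), v2 surface water (wet seasons only), v3
# artificial water points, v4 slope, v5 lag-weighted conflict, v6
# ethnic-border proximity.

#' Sentinel score assigned to unsuitable cells
#'
#' Unsuitable cells (open water, bare soil) receive `-Inf` in the
#' favorability surface so they are never selected as movement targets.
#' @export
UNSUITABLE_SCORE <- -Inf

#' Soil-Adjusted Vegetation Index
#'
#' SAVI = (1 + L) * (NIR - Red) / (NIR + Red + L), the standard correction
#' of NDVI for soil brightness in sparse-canopy arid land. The canopy
#' background adjustment L defaults to 0.5.
#'
#' @param nir,red aligned [RasterGrid-class] reflectance layers.
#' @param L canopy background adjustment, >= 0 (default 0.5).
#' @return a [RasterGrid-class] of SAVI values; cells where
#'   NIR + Red + L == 0 become nodata.
#' @examples
#' nir <- rasterGrid(matrix(0.4, 1, 1)); red <- rasterGrid(matrix(0.2, 1, 1))
#' gridValues(computeSavi(nir, red))  # 1.5 * 0.2 / 1.1
#' @export
computeSavi <- function(nir, red, L = 0.5) {
  if (L < 0) stop("L must be non-negative")
  .stopIfMisaligned(nir, red, "NIR and Red layers")
  den <- nir@values + red@values + L
  out <- (1 + L) * (nir@values - red@values) / den
  out[den == 0] <- NA
  rasterGrid(out, nir@cellSize, nir@origin)
}

#' Per-cell median composite over a season's scenes
#'
#' Aggregates all scenes of one season to their per-cell median, ignoring
#' nodata; a cell is nodata only when it is nodata in every scene.
#'
#' @param scenes non-empty list of aligned [RasterGrid-class] objects.
#' @return a [RasterGrid-class].
#' @export
seasonalMedianComposite <- function(scenes) {
  if (length(scenes) == 0) stop("empty scene list")
  ref <- scenes[[1]]
  for (s in scenes[-1]) .stopIfMisaligned(ref, s, "scenes")
  if (length(scenes) == 1) return(rasterGrid(ref@values, ref@cellSize,
                                             ref@origin))
  arr <- vapply(scenes, gridValues,
                matrix(0, nRows(ref), nCols(ref)))
  med <- apply(arr, c(1, 2), function(z) {
    if (all(is.na(z))) NA_real_ else median(z, na.rm = TRUE)
  })
  rasterGrid(med, ref@cellSize, ref@origin)
}

# per-cell event counts for one season (by season index)
.seasonCellCounts <- function(events, sIdx, template) {
  m <- matrix(0, nRows(template), nCols(template))
  if (is.null(events) || nrow(events) == 0) return(list(counts = m,
                                                        dropped = 0L))
  eIdx <- vapply(seq_len(nrow(events)), function(i)
    seasonIndex(seasonOfMonth(events$month[i], events$year[i])), integer(1))
  sel <- events[eIdx == sIdx, , drop = FALSE]
  dropped <- 0L
  if (nrow(sel)) {
    rc <- pointToCell(template, sel$x, sel$y)
    ok <- !is.na(rc$row)
    dropped <- sum(!ok)
    if (any(ok)) {
      idx <- cbind(rc$row[ok], rc$col[ok])
      for (i in seq_len(nrow(idx)))
        m[idx[i, 1], idx[i, 2]] <- m[idx[i, 1], idx[i, 2]] + 1
    }
  }
  list(counts = m, dropped = dropped)
}

#' Seasonal conflict surface with a one-season lag
#'
#' Raw per-cell score = (events this season) + `lagWeight` * (events the
#' immediately preceding season); the layer returned is raw / `globalMax`,
#' clipped to [0, 1]. `globalMax` should be the maximum raw score over the
#' whole simulation window (see [conflictGlobalMax()]) so that intensity is
#' comparable across seasons.
#'
#' @param events data.frame with columns `x`, `y` (planar meters), `year`,
#'   `month`; events outside the grid extent are dropped with a message.
#' @param season a [SeasonId-class].
#' @param template a [RasterGrid-class] defining the grid.
#' @param lagWeight carry-over weight of last season's events, in [0, 1]
#'   (default 0.5: half the effect).
#' @param globalMax positive normalization constant.
#' @return a [RasterGrid-class] in [0, 1].
#' @export
conflictSurface <- function(events, season, template, lagWeight = 0.5,
                            globalMax) {
  if (lagWeight < 0 || lagWeight > 1)
    stop("lagWeight must lie in [0, 1]")
  if (!is.numeric(globalMax) || globalMax <= 0)
    stop("globalMax must be positive")
  sIdx <- seasonIndex(season)
  cur <- .seasonCellCounts(events, sIdx, template)
  prev <- .seasonCellCounts(events, sIdx - 1L, template)
  if (cur$dropped + prev$dropped > 0)
    message(sprintf("conflictSurface: dropped %d event(s) outside the grid",
                    cur$dropped + prev$dropped))
  raw <- cur$counts + lagWeight * prev$counts
  rasterGrid(pmin(raw / globalMax, 1), template@cellSize, template@origin)
}

#' Global maximum of the lag-weighted conflict score
#'
#' Pre-pass over every season touched by the simulation window, returning
#' the largest per-cell raw score (current + lag-weighted previous counts).
#'
#' @inheritParams conflictSurface
#' @param seasons list of [SeasonId-class] covering the window.
#' @return a positive scalar (at least 1 so an all-quiet window still
#'   normalizes sanely).
#' @export
conflictGlobalMax <- function(events, seasons, template, lagWeight = 0.5) {
  counts <- list()
  idx <- vapply(seasons, seasonIndex, integer(1))
  need <- sort(unique(c(idx, idx - 1L)))
  for (i in need)
    counts[[as.character(i)]] <- .seasonCellCounts(events, i, template)$counts
  gmax <- 0
  for (i in idx) {
    raw <- counts[[as.character(i)]] +
      lagWeight * counts[[as.character(i - 1L)]]
    gmax <- max(gmax, max(raw))
  }
  max(gmax, 1)
}

#' Ethnic-border proximity surface
#'
#' Cells crossed by a border line score `weights[1]` (1.0); cells whose
#' centers fall within the first buffer distance score `weights[2]` (0.5);
#' within the second, `weights[3]` (0.25); 0 beyond. Buffer distances are in
#' kilometers (10 / 20 km defaults, i.e. a 20 km gradient buffer).
#'
#' @param borders either a segment matrix (columns x1, y1, x2, y2, meters)
#'   or a list of polygon vertex matrices whose edges are the borders.
#' @param template a [RasterGrid-class].
#' @param bufferDistsKm two increasing buffer distances, km.
#' @param weights three descending weights (border cell, first ring,
#'   second ring).
#' @return a [RasterGrid-class] in [0, 1].
#' @export
ethnicBorderSurface <- function(borders, template,
                                bufferDistsKm = c(10, 20),
                                weights = c(1.0, 0.5, 0.25)) {
  if (is.list(borders) && !is.matrix(borders)) {
    segs <- matrix(numeric(0), 0, 4)
    for (ring in borders) {
      n <- nrow(ring)
      for (k in seq_len(n)) {
        j <- if (k == n) 1L else k + 1L
        segs <- rbind(segs, c(ring[k, ], ring[j, ]))
      }
    }
    borders <- segs
  }
  nr <- nRows(template); nc <- nCols(template); cs <- template@cellSize
  if (is.null(borders) || nrow(borders) == 0) {
    warning("empty border geometry: returning an all-zero layer")
    return(rasterGrid(matrix(0, nr, nc), cs, template@origin))
  }
  cc <- cellCenters(template)
  X <- matrix(cc$x, nr, nc, byrow = TRUE)
  Y <- matrix(cc$y, nr, nc)
  d <- distanceToSegments(as.vector(X), as.vector(Y), borders)
  out <- numeric(length(d))
  out[d <= bufferDistsKm[2] * 1000] <- weights[3]
  out[d <= bufferDistsKm[1] * 1000] <- weights[2]
  # border cells: exact segment-rectangle test, only near-border candidates
  halfDiag <- cs * sqrt(2) / 2
  cand <- which(d <= halfDiag + 1e-9)
  for (i in cand) {
    r <- (i - 1L) %% nr + 1L; cl <- (i - 1L) %/% nr + 1L
    xmin <- template@origin[1] + (cl - 1) * cs
    ymax <- template@origin[2] - (r - 1) * cs
    hit <- FALSE
    for (k in seq_len(nrow(borders))) {
      if (segmentIntersectsRect(borders[k, 1], borders[k, 2],
                                borders[k, 3], borders[k, 4],
                                xmin, xmin + cs, ymax - cs, ymax)) {
        hit <- TRUE; break
      }
    }
    if (hit) out[i] <- weights[1]
  }
  rasterGrid(matrix(out, nr, nc), cs, template@origin)
}

#' Surface-water and water-point layers
#'
#' `v2` is the binary surface-water mask in wet seasons and identically zero
#' in dry seasons (pastoralists rely on wells and boreholes then); `v3` is
#' the min-max normalized per-cell count of artificial water points, so
#' cells holding several sources score higher than single-source cells.
#'
#' @param surfaceWaterMask binary [RasterGrid-class] (1 = water present).
#' @param waterPoints data.frame/matrix with `x`, `y` planar meters (may
#'   have zero rows).
#' @param season a [SeasonId-class].
#' @return list with elements `v2` and `v3` ([RasterGrid-class]).
#' @export
waterLayers <- function(surfaceWaterMask, waterPoints, season) {
  v <- surfaceWaterMask@values
  if (!all(v %in% c(0, 1) | is.na(v)))
    stop("surfaceWaterMask must be binary 0/1")
  v2vals <- if (isWet(season)) v else {
    z <- v; z[!is.na(z)] <- 0; z
  }
  v2 <- rasterGrid(v2vals, surfaceWaterMask@cellSize,
                   surfaceWaterMask@origin)
  counts <- matrix(0, nRows(surfaceWaterMask), nCols(surfaceWaterMask))
  wp <- as.data.frame(waterPoints)
  if (nrow(wp)) {
    rc <- pointToCell(surfaceWaterMask, wp$x, wp$y)
    ok <- !is.na(rc$row)
    for (i in which(ok))
      counts[rc$row[i], rc$col[i]] <- counts[rc$row[i], rc$col[i]] + 1
  }
  v3 <- suppressWarnings(normalizeLayer(
    rasterGrid(counts, surfaceWaterMask@cellSize, surfaceWaterMask@origin)))
  list(v2 = v2, v3 = v3)
}

#' Slope surface from elevation (Horn's method)
#'
#' Horn's 3x3 finite-difference gradient on the elevation grid, expressed in
#' degrees, with edge rows/columns replicated. By default the result is
#' min-max normalized to [0, 1] (the steepest cell maps to 1).
#'
#' @param elevation a [RasterGrid-class] of elevations in meters.
#' @param normalize normalize to [0, 1] (default TRUE); FALSE returns
#'   degrees.
#' @return a [RasterGrid-class].
#' @export
slopeSurface <- function(elevation, normalize = TRUE) {
  z <- elevation@values
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 3 || nc < 3) stop("elevation grid must be at least 3 x 3")
  cs <- elevation@cellSize
  # edge-replicated padding
  zp <- z[c(1, 1:nr, nr), c(1, 1:nc, nc)]
  a <- zp[1:nr, 1:nc];       b <- zp[1:nr, 2:(nc + 1)];  cc <- zp[1:nr, 3:(nc + 2)]
  d <- zp[2:(nr + 1), 1:nc];                             f <- zp[2:(nr + 1), 3:(nc + 2)]
  g <- zp[3:(nr + 2), 1:nc]; h <- zp[3:(nr + 2), 2:(nc + 1)]; i <- zp[3:(nr + 2), 3:(nc + 2)]
  dzdx <- ((cc + 2 * f + i) - (a + 2 * d + g)) / (8 * cs)
  dzdy <- ((g + 2 * h + i) - (a + 2 * b + cc)) / (8 * cs)
  deg <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  out <- rasterGrid(deg, cs, elevation@origin)
  if (normalize) suppressWarnings(normalizeLayer(out)) else out
}

#' Land-tenure (private-land) mask
#'
#' A cell is private iff its center lies within `cityRadiusKm` of a city
#' centroid or `townRadiusKm` of a town centroid (14 / 4 km defaults chosen
#' to keep roughly 80% of land public); all other cells are public.
#'
#' @param settlements data.frame with `x`, `y` (planar meters) and
#'   `sizeClass` in `{"city", "town"}`.
#' @param template a [RasterGrid-class].
#' @param cityRadiusKm,townRadiusKm private-land radii in km.
#' @return a binary [RasterGrid-class] (1 = private).
#' @export
tenureMask <- function(settlements, template, cityRadiusKm = 14,
                       townRadiusKm = 4) {
  nr <- nRows(template); nc <- nCols(template)
  priv <- matrix(0, nr, nc)
  st <- as.data.frame(settlements)
  if (nrow(st)) {
    if (!all(st$sizeClass %in% c("city", "town")))
      stop("sizeClass must be 'city' or 'town'")
    cc <- cellCenters(template)
    X <- matrix(cc$x, nr, nc, byrow = TRUE)
    Y <- matrix(cc$y, nr, nc)
    for (i in seq_len(nrow(st))) {
      rKm <- if (st$sizeClass[i] == "city") cityRadiusKm else townRadiusKm
      priv[(X - st$x[i])^2 + (Y - st$y[i])^2 <= (rKm * 1000)^2] <- 1
    }
  }
  rasterGrid(priv, template@cellSize, template@origin)
}

#' Assemble an EnvironmentStack
#'
#' @param v1,v2,v3,v4,v5,v6 component [RasterGrid-class] layers in [0, 1].
#' @param privateMask,suitabilityMask binary [RasterGrid-class] masks.
#' @param season a [SeasonId-class].
#' @return an [EnvironmentStack-class].
#' @export
environmentStack <- function(v1, v2, v3, v4, v5, v6, privateMask,
                             suitabilityMask, season) {
  new("EnvironmentStack", v1 = v1, v2 = v2, v3 = v3, v4 = v4, v5 = v5,
      v6 = v6, privateMask = privateMask, suitabilityMask = suitabilityMask,
      season = season)
}

setMethod("show", "EnvironmentStack", function(object) {
  cat(sprintf("EnvironmentStack (%s %d, %s): %d x %d cells\n",
              object@season@name, object@season@year,
              if (isWet(object@season)) "wet" else "dry",
              nRows(object@v1), nCols(object@v1)))
  cat(sprintf("  private land: %.1f%%; suitable: %.1f%%\n",
              100 * mean(object@privateMask@values, na.rm = TRUE),
              100 * mean(object@suitabilityMask@values, na.rm = TRUE)))
  invisible(object)
})

#' Additive favorability score of an environment stack
#'
#' score = w1*v1 + w2*v2 + w3*v3 + w4*v4 + w5*v5 + w6*v6 with the default
#' signed weights (+1, +1, +1, -0.25, -1, -0.25), i.e.
#' v1 + v2 + v3 - 0.25*v4 - v5 - 0.25*v6, giving scores in [-1.5, 3].
#' Cells failing the suitability mask receive [UNSUITABLE_SCORE] and are
#' never selectable as movement targets.
#'
#' @param stack an [EnvironmentStack-class].
#' @param weights numeric(6) signed coefficients of (v1..v6).
#' @return a [RasterGrid-class] of scores.
#' @export
favorabilitySurface <- function(stack,
                                weights = c(1, 1, 1, -0.25, -1, -0.25)) {
  stopifnot(length(weights) == 6)
  validObject(stack)
  s <- weights[1] * stack@v1@values + weights[2] * stack@v2@values +
    weights[3] * stack@v3@values + weights[4] * stack@v4@values +
    weights[5] * stack@v5@values + weights[6] * stack@v6@values
  s[stack@suitabilityMask@values == 0] <- UNSUITABLE_SCORE
  rasterGrid(s, stack@v1@cellSize, stack@v1@origin)
}
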