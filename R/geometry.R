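# Planar geometry primitives used by the landscape and analysis modules:
# point-in-polygon containment, point/segment distance, segment-rectangle
# intersection, convex-polygon half-plane clipping, bounded Voronoi
# tessellation, and GeoJSON polygon I/O. Polygons are simple single-ring
# features stored as two-column (x, y) matrices in planar meters; a set of
# polygons is a named list of such matrices.

#' Point-in-polygon containment (ray casting)
#'
#' Boundary-inclusive: points lying exactly on a polygon edge count as
#' inside, which makes the district-assignment rule deterministic (a point
#' on a shared border belongs to the first district in list order).
#'
#' @param x,y point coordinates (vectors).
#' @param ring two-column matrix of polygon vertices (closed implicitly).
#' @return logical vector.
#' @export
pointInPolygon <- function(x, y, ring) {
  px <- ring[, 1]; py <- ring[, 2]
  n <- length(px)
  jj <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(x))
  onEdge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- px[jj[k]]; y1 <- py[jj[k]]; x2 <- px[k]; y2 <- py[k]
    # edge membership (collinear and within the segment bounding box)
    cr <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
    scale <- max(abs(c(x1, x2, y1, y2, 1)))
    on <- abs(cr) <= 1e-9 * scale * scale &
      x >= pmin(x1, x2) - 1e-9 & x <= pmax(x1, x2) + 1e-9 &
      y >= pmin(y1, y2) - 1e-9 & y <= pmax(y1, y2) + 1e-9
    onEdge <- onEdge | on
    crosses <- ((y1 > y) != (y2 > y))
    xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
    inside <- xor(inside, crosses & x < xint)
  }
  inside | onEdge
}

#' Distance from points to a polyline segment set
#'
#' @param x,y point coordinates (vectors).
#' @param segments matrix with columns x1, y1, x2, y2 (one row per segment).
#' @return numeric vector: distance in the same planar units to the nearest
#'   segment (Inf when `segments` is empty).
#' @export
distanceToSegments <- function(x, y, segments) {
  d <- rep(Inf, length(x))
  if (is.null(segments) || nrow(segments) == 0) return(d)
  for (k in seq_len(nrow(segments))) {
    x1 <- segments[k, 1]; y1 <- segments[k, 2]
    x2 <- segments[k, 3]; y2 <- segments[k, 4]
    dx <- x2 - x1; dy <- y2 - y1
    L2 <- dx * dx + dy * dy
    t <- if (L2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - x1) * dx + (y - y1) * dy) / L2))
    dk <- sqrt((x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2)
    d <- pmin(d, dk)
  }
  d
}

# Liang-Barsky: does the segment (x1,y1)-(x2,y2) intersect the axis-aligned
# rectangle [xmin,xmax] x [ymin,ymax]?
segmentIntersectsRect <- function(x1, y1, x2, y2, xmin, xmax, ymin, ymax) {
  dx <- x2 - x1; dy <- y2 - y1
  p <- c(-dx, dx, -dy, dy)
  q <- c(x1 - xmin, xmax - x1, y1 - ymin, ymax - y1)
  t0 <- 0; t1 <- 1
  for (i in 1:4) {
    if (p[i] == 0) {
      if (q[i] < 0) return(FALSE)
    } else {
      r <- q[i] / p[i]
      if (p[i] < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# Sutherland-Hodgman clip of a convex ring by the half-plane
# {p : (p - a) . n <= c}; used to build bounded Voronoi cells.
clipHalfPlane <- function(ring, nx, ny, c0) {
  n <- nrow(ring)
  if (n == 0) return(ring)
  out <- matrix(numeric(0), 0, 2)
  sgn <- ring[, 1] * nx + ring[, 2] * ny - c0
  for (k in seq_len(n)) {
    j <- if (k == 1) n else k - 1L
    cur <- ring[k, ]; prev <- ring[j, ]
    curIn <- sgn[k] <= 1e-9; prevIn <- sgn[j] <= 1e-9
    if (curIn) {
      if (!prevIn) {
        t <- sgn[j] / (sgn[j] - sgn[k])
        out <- rbind(out, prev + t * (cur - prev))
      }
      out <- rbind(out, cur)
    } else if (prevIn) {
      t <- sgn[j] / (sgn[j] - sgn[k])
      out <- rbind(out, prev + t * (cur - prev))
    }
  }
  out
}

#' Bounded Voronoi tessellation of a rectangle
#'
#' Exact convex Voronoi cells of `seeds` clipped to the rectangle, computed
#' by iterated half-plane (perpendicular-bisector) clipping. The cells are
#' contiguous, non-overlapping, and cover the rectangle: the standard way to
#' fabricate synthetic administrative tessellations.
#'
#' @param seeds two-column matrix of seed points (one polygon per seed).
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return named list of two-column vertex matrices (names `"D1"`, ... or
#'   the rownames of `seeds`).
#' @export
voronoiPolygons <- function(seeds, xmin, xmax, ymin, ymax) {
  n <- nrow(seeds)
  box <- cbind(c(xmin, xmax, xmax, xmin), c(ymin, ymin, ymax, ymax))
  polys <- vector("list", n)
  for (i in seq_len(n)) {
    ring <- box
    for (j in seq_len(n)) {
      if (i == j) next
      # keep the side of the bisector nearer seed i
      nx <- seeds[j, 1] - seeds[i, 1]
      ny <- seeds[j, 2] - seeds[i, 2]
      mid <- (seeds[i, ] + seeds[j, ]) / 2
      ring <- clipHalfPlane(ring, nx, ny, nx * mid[1] + ny * mid[2])
      if (nrow(ring) == 0) break
    }
    polys[[i]] <- ring
  }
  names(polys) <- if (!is.null(rownames(seeds))) rownames(seeds) else
    paste0("D", seq_len(n))
  polys
}

# Interior edges of a polygon set (edges not lying on the bounding box),
# as a segment matrix (x1, y1, x2, y2). Used for ethnic-territory borders.
interiorEdges <- function(polys, xmin, xmax, ymin, ymax, tol = 1e-6) {
  segs <- matrix(numeric(0), 0, 4)
  onBox <- function(p1, p2) {
    both <- function(v, lim) abs(v - lim) < tol
    (both(p1[1], xmin) && both(p2[1], xmin)) ||
      (both(p1[1], xmax) && both(p2[1], xmax)) ||
      (both(p1[2], ymin) && both(p2[2], ymin)) ||
      (both(p1[2], ymax) && both(p2[2], ymax))
  }
  for (ring in polys) {
    n <- nrow(ring)
    for (k in seq_len(n)) {
      j <- if (k == n) 1L else k + 1L
      if (!onBox(ring[k, ], ring[j, ]))
        segs <- rbind(segs, c(ring[k, ], ring[j, ]))
    }
  }
  segs
}

# ---- GeoJSON I/O ------------------------------------------------------------

#' Read / write simple polygon sets as GeoJSON
#'
#' Supports FeatureCollections of single-ring Polygon features with a `name`
#' property — sufficient for district and ethnic-territory tessellations.
#' Coordinates are planar meters (the package works in a projected CRS).
#'
#' @param path file path.
#' @param polys named list of two-column vertex matrices (for writing).
#' @return `readGeoJSONPolygons` returns a named list of vertex matrices.
#' @export
readGeoJSONPolygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  out <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon"))
      stop("only Polygon features are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    # drop the GeoJSON closing vertex (first repeated last)
    if (nrow(m) > 1 && all(abs(m[1, ] - m[nrow(m), ]) < 1e-9))
      m <- m[-nrow(m), , drop = FALSE]
    nm <- if (!is.null(f$properties$name)) f$properties$name else
      paste0("poly", length(out) + 1L)
    out[[nm]] <- m
  }
  out
}

#' @rdname readGeoJSONPolygons
#' @export
writeGeoJSONPolygons <- function(polys, path) {
  features <- lapply(names(polys), function(nm) {
    ring <- polys[[nm]]
    ringC <- rbind(ring, ring[1, ])
    coords <- list(lapply(seq_len(nrow(ringC)),
                          function(i) c(ringC[i, 1], ringC[i, 2])))
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
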