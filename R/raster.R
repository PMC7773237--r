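# RasterGrid construction, accessors, alignment, normalization, and the
# plain-text (ESRI ASCII grid) I/O used for all on-disk rasters.

#' Create a RasterGrid
#'
#' @param values numeric matrix; `NA` marks nodata. Row 1 is the
#'   northernmost row.
#' @param cellSize cell edge length in meters (default 1000).
#' @param origin numeric(2): planar (x, y) of the top-left corner, meters.
#' @return a [RasterGrid-class].
#' @examples
#' g <- rasterGrid(matrix(1:12, 3, 4))
#' nRows(g); nCols(g)
#' @export
rasterGrid <- function(values, cellSize = 1000, origin = c(0, 0)) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = as.numeric(cellSize),
      origin = as.numeric(origin))
}

#' @rdname RasterGrid-class
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname RasterGrid-class
#' @export
setReplaceMethod("gridValues", "RasterGrid", function(x, value) {
  if (!is.matrix(value) || !all(dim(value) == dim(x@values)))
    stop("replacement values must be a matrix of identical shape")
  x@values <- value
  storage.mode(x@values) <- "double"
  x
})

#' @rdname RasterGrid-class
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname RasterGrid-class
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname RasterGrid-class
#' @export
setMethod("nRows", "RasterGrid", function(x) nrow(x@values))

#' @rdname RasterGrid-class
#' @export
setMethod("nCols", "RasterGrid", function(x) ncol(x@values))

#' @rdname isAligned
#' @export
setMethod("isAligned", signature("RasterGrid", "RasterGrid"), function(x, y) {
  isTRUE(all.equal(x@cellSize, y@cellSize, tolerance = 1e-9)) &&
    isTRUE(all.equal(x@origin, y@origin, tolerance = 1e-9)) &&
    all(dim(x@values) == dim(y@values))
})

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  rng <- if (all(is.na(v))) c(NA, NA) else range(v, na.rm = TRUE)
  cat(sprintf("RasterGrid: %d x %d cells, %.0f m resolution\n",
              nrow(v), ncol(v), object@cellSize))
  cat(sprintf("  origin (top-left): (%.1f, %.1f) m\n",
              object@origin[1], object@origin[2]))
  cat(sprintf("  values: [%s, %s], %d nodata cell(s)\n",
              format(rng[1]), format(rng[2]), sum(is.na(v))))
  invisible(object)
})

.stopIfMisaligned <- function(x, y, what = "layers") {
  if (!isAligned(x, y))
    stop(sprintf("%s are not aligned (origin, cell size and shape must match)",
                 what), call. = FALSE)
  invisible(TRUE)
}

#' Planar coordinates of cell centers
#'
#' @param grid a [RasterGrid-class].
#' @return list with `x` (length nCols) and `y` (length nRows) center
#'   coordinates in meters; `y` decreases with row index (row 1 is north).
#' @export
cellCenters <- function(grid) {
  cs <- grid@cellSize
  list(x = grid@origin[1] + (seq_len(nCols(grid)) - 0.5) * cs,
       y = grid@origin[2] - (seq_len(nRows(grid)) - 0.5) * cs)
}

#' Map planar points to grid cells
#'
#' @param grid a [RasterGrid-class].
#' @param x,y planar coordinates in meters.
#' @return data.frame with `row`, `col` (NA when the point falls outside the
#'   grid extent).
#' @export
pointToCell <- function(grid, x, y) {
  cs <- grid@cellSize
  col <- floor((x - grid@origin[1]) / cs) + 1
  row <- floor((grid@origin[2] - y) / cs) + 1
  bad <- row < 1 | row > nRows(grid) | col < 1 | col > nCols(grid) |
    !is.finite(row) | !is.finite(col)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Min-max normalize a layer to [0, 1]
#'
#' Applies (v - min) / (max - min) over the non-nodata cells. Nodata is
#' preserved. A constant layer (max == min) normalizes to all zeros with a
#' warning; an all-nodata layer is an error.
#'
#' @param raw a [RasterGrid-class].
#' @return an aligned [RasterGrid-class] with values in [0, 1].
#' @examples
#' g <- rasterGrid(matrix(c(2, 4, 10, NA), 2, 2))
#' gridValues(normalizeLayer(g))
#' @export
normalizeLayer <- function(raw) {
  v <- raw@values
  if (all(is.na(v))) stop("empty layer: every cell is nodata")
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  if (hi == lo) {
    warning("degenerate constant layer: normalizing to all zeros")
    out <- v
    out[!is.na(out)] <- 0
  } else {
    out <- (v - lo) / (hi - lo)
  }
  rasterGrid(out, raw@cellSize, raw@origin)
}

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Read / write a raster as an ESRI ASCII grid
#'
#' The plain-text grid interchange format: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `nodata_value`) followed by
#' whitespace-separated rows, north row first. The nodata tag is honored in
#' both directions (`NA` internally).
#'
#' @param path file path.
#' @param grid a [RasterGrid-class] (for writing).
#' @param nodata numeric sentinel written for `NA` cells (default -9999).
#' @return `readAsciiGrid` returns a [RasterGrid-class];
#'   `writeAsciiGrid` invisibly returns `path`.
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop("ASCII grid body does not match header dimensions")
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  rasterGrid(m, hdr$cellsize, origin)
}

#' @rdname readAsciiGrid
#' @export
writeAsciiGrid <- function(grid, path, nodata = -9999) {
  v <- grid@values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(sprintf("ncols %d", nc),
           sprintf("nrows %d", nr),
           sprintf("xllcorner %.10g", grid@origin[1]),
           sprintf("yllcorner %.10g", grid@origin[2] - nr * grid@cellSize),
           sprintf("cellsize %.10g", grid@cellSize),
           sprintf("nodata_value %.10g", nodata))
  v[is.na(v)] <- nodata
  body <- apply(v, 1, function(r) paste(format(r, trim = TRUE,
                                               digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
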