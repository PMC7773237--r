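#' @rdname RasterGrid-class
#' @param x,object a [RasterGrid-class] (or other package object).
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-class
#' @param value replacement value matrix.
#' @export
setGeneric("gridValues<-", function(x, value) standardGeneric("gridValues<-"))

#' @rdname RasterGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname RasterGrid-class
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname RasterGrid-class
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))

#' Test whether two grids share origin, cell size and shape
#'
#' All layer algebra in the package requires alignment in this sense.
#'
#' @param x,y two [RasterGrid-class] objects.
#' @return `TRUE` or `FALSE`.
#' @export
setGeneric("isAligned", function(x, y) standardGeneric("isAligned"))

#' @rdname SeasonId-class
#' @param x a [SeasonId-class].
#' @export
setGeneric("isWet", function(x) standardGeneric("isWet"))

#' @rdname SeasonId-class
#' @export
setGeneric("seasonIndex", function(x) standardGeneric("seasonIndex"))
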