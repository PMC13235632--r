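#' Storage-backed 2D data set
#'
#' The central container: an N1 x N2 grid of raw transients or processed
#' spectra, with one \code{\linkS4class{AxisSpec}} per dimension, the
#' acquisition parameters, a processing-stage tag and a provenance list
#' (config snapshot). The grid is held as one or more named real planes
#' (\code{"r"}; \code{"r","i"} for complex stages; \code{"rr","ri","ir","ii"}
#' for hypercomplex data), each a \code{\linkS4class{GridBackend}}, so values
#' are only ever materialized one row or one column block at a time.
#'
#' Stage tags: \code{raw}, \code{apodized}, \code{f2-transformed},
#' \code{fully-transformed-absorption}, \code{fully-transformed-magnitude}.
#'
#' @slot planes named list of \code{GridBackend}s, identical dimensions.
#' @slot axis1 row axis (t1 / precursor dimension).
#' @slot axis2 column axis (t2 / fragment dimension).
#' @slot stage processing stage tag.
#' @slot params the \code{\linkS4class{AcquisitionParams}}.
#' @slot provenance list snapshot of the configuration that produced the data.
#' @export
setClass("Dataset2D",
  representation(planes = "list", axis1 = "AxisSpec", axis2 = "AxisSpec",
                 stage = "character", params = "AcquisitionParams",
                 provenance = "list"))

.DATASET_STAGES <- c("raw", "apodized", "f2-transformed",
                     "fully-transformed-absorption",
                     "fully-transformed-magnitude")

setValidity("Dataset2D", function(object) {
  msg <- character()
  if (!length(object@planes) || is.null(names(object@planes)))
    msg <- c(msg, "planes must be a named non-empty list")
  dims <- lapply(object@planes, backendDims)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all planes must share dimensions")
  d <- dims[[1]]
  if (d[1] != object@axis1@nPoints)
    msg <- c(msg, sprintf("grid has %d rows but axis1 has %d points",
                          d[1], object@axis1@nPoints))
  if (d[2] != object@axis2@nPoints)
    msg <- c(msg, sprintf("grid has %d columns but axis2 has %d points",
                          d[2], object@axis2@nPoints))
  if (!object@stage %in% .DATASET_STAGES)
    msg <- c(msg, paste("unknown stage:", object@stage))
  if (length(msg)) msg else TRUE
})

#' Construct a Dataset2D
#' @param planes named list of \code{GridBackend}s (e.g. \code{list(r = ...)}).
#' @param axis1,axis2 row and column \code{AxisSpec}s.
#' @param stage stage tag.
#' @param params \code{AcquisitionParams}.
#' @param provenance list snapshot of processing parameters.
#' @return a \code{Dataset2D}.
#' @export
dataset2d <- function(planes, axis1, axis2, stage, params, provenance = list()) {
  new("Dataset2D", planes = planes, axis1 = axis1, axis2 = axis2,
      stage = stage, params = params, provenance = provenance)
}

#' Grid dimensions, axes, stage and parameters of a Dataset2D
#' @param x a \code{Dataset2D}.
#' @return \code{gridDims}: integer (N1, N2); \code{datasetStage}: the stage
#'   tag; \code{datasetParams}: the \code{AcquisitionParams}; \code{rowAxis} /
#'   \code{colAxis}: the \code{AxisSpec}s; \code{planeNames}: plane names.
#' @export
gridDims <- function(x) backendDims(x@planes[[1]])

#' @rdname gridDims
#' @export
datasetStage <- function(x) x@stage

#' @rdname gridDims
#' @export
datasetParams <- function(x) x@params

#' @rdname gridDims
#' @export
rowAxis <- function(x) x@axis1

#' @rdname gridDims
#' @export
colAxis <- function(x) x@axis2

#' @rdname gridDims
#' @export
planeNames <- function(x) names(x@planes)

.checkIndex <- function(i, n, what) {
  if (length(i) != 1L || is.na(i) || i < 1L || i > n)
    stop(sprintf("index error: %s index %s out of range [1, %d]",
                 what, as.character(i), n))
  as.integer(i)
}

.rowValues <- function(x, i, plane) {
  if (!is.null(plane)) return(readRowValues(x@planes[[plane]], i))
  if (all(c("r", "i") %in% names(x@planes)))
    complex(real = readRowValues(x@planes[["r"]], i),
            imaginary = readRowValues(x@planes[["i"]], i))
  else readRowValues(x@planes[["r"]], i)
}

.colValues <- function(x, j, plane) {
  if (!is.null(plane)) return(as.numeric(readColBlock(x@planes[[plane]], j, 1L)))
  if (all(c("r", "i") %in% names(x@planes)))
    complex(real = as.numeric(readColBlock(x@planes[["r"]], j, 1L)),
            imaginary = as.numeric(readColBlock(x@planes[["i"]], j, 1L)))
  else as.numeric(readColBlock(x@planes[["r"]], j, 1L))
}

#' Row and column access for 2D data sets
#'
#' The only sanctioned way to get values in and out of a
#' \code{\linkS4class{Dataset2D}}: whole rows and whole columns, as
#' \code{\linkS4class{Scan}} objects carrying the matching axis. A
#' \code{putRow} followed by \code{getRow} is the identity.
#'
#' @param x a \code{Dataset2D}.
#' @param i row index, \code{j} column index (1-based).
#' @param value a \code{Scan} or bare numeric/complex vector.
#' @param plane plane name to access a single real plane of complex /
#'   hypercomplex data; \code{NULL} combines \code{"r"}/\code{"i"} into a
#'   complex scan when both exist.
#' @param ... unused.
#' @return \code{getRow}/\code{getCol} return a \code{Scan}; \code{putRow}/
#'   \code{putCol} return the data set invisibly.
#' @name dataset2d-access
NULL

#' @rdname dataset2d-access
#' @export
setMethod("getRow", "Dataset2D", function(x, i, plane = NULL, ...) {
  i <- .checkIndex(i, gridDims(x)[1], "row")
  scan1d(.rowValues(x, i, plane), x@axis2, origin = sprintf("row %d", i))
})

#' @rdname dataset2d-access
#' @export
setMethod("getCol", "Dataset2D", function(x, j, plane = NULL, ...) {
  j <- .checkIndex(j, gridDims(x)[2], "column")
  scan1d(.colValues(x, j, plane), x@axis1, origin = sprintf("column %d", j))
})

.scanOrVector <- function(value) {
  if (is(value, "Scan")) value@values else value
}

#' @rdname dataset2d-access
#' @export
setMethod("putRow", "Dataset2D", function(x, i, value, plane = NULL, ...) {
  i <- .checkIndex(i, gridDims(x)[1], "row")
  v <- .scanOrVector(value)
  if (length(v) != gridDims(x)[2])
    stop(sprintf("dimension error: row of length %d for grid with %d columns",
                 length(v), gridDims(x)[2]))
  if (is.complex(v)) {
    writeRowValues(x@planes[["r"]], i, Re(v))
    writeRowValues(x@planes[["i"]], i, Im(v))
  } else {
    writeRowValues(x@planes[[if (is.null(plane)) "r" else plane]], i, v)
  }
  invisible(x)
})

#' @rdname dataset2d-access
#' @export
setMethod("putCol", "Dataset2D", function(x, j, value, plane = NULL, ...) {
  j <- .checkIndex(j, gridDims(x)[2], "column")
  v <- .scanOrVector(value)
  if (length(v) != gridDims(x)[1])
    stop(sprintf("dimension error: column of length %d for grid with %d rows",
                 length(v), gridDims(x)[1]))
  if (is.complex(v)) {
    writeColBlock(x@planes[["r"]], j, matrix(Re(v), ncol = 1L))
    writeColBlock(x@planes[["i"]], j, matrix(Im(v), ncol = 1L))
  } else {
    writeColBlock(x@planes[[if (is.null(plane)) "r" else plane]], j,
                  matrix(v, ncol = 1L))
  }
  invisible(x)
})

#' Create an empty file-backed data set
#'
#' Allocates zero-filled planes in a scratch directory (or in-memory for
#' small grids when \code{backing = "memory"}).
#'
#' @param n1,n2 grid dimensions.
#' @param axis1,axis2 axes.
#' @param stage stage tag.
#' @param params \code{AcquisitionParams}.
#' @param planes character vector of plane names.
#' @param backing \code{"file"} or \code{"memory"}.
#' @param dir directory for file backing (default \code{tempdir()}).
#' @param provenance provenance list.
#' @return a \code{Dataset2D}.
#' @export
emptyDataset2d <- function(n1, n2, axis1, axis2, stage, params,
                           planes = "r", backing = c("file", "memory"),
                           dir = tempdir(), provenance = list()) {
  backing <- match.arg(backing)
  pl <- lapply(planes, function(p) {
    if (backing == "memory") memoryBackend(matrix(0, n1, n2))
    else fileBackend(tempfile(pattern = sprintf("grid_%s_", p), tmpdir = dir,
                              fileext = ".f64"),
                     n1, n2, bytes = 8L, create = TRUE)
  })
  names(pl) <- planes
  dataset2d(pl, axis1, axis2, stage, params, provenance)
}

setMethod("show", "Dataset2D", function(object) {
  d <- gridDims(object)
  cat(sprintf("Dataset2D [%s]: %d x %d, planes: %s\n", object@stage,
              d[1], d[2], paste(names(object@planes), collapse = ",")))
  cat("  axis1: "); show(object@axis1)
  cat("  axis2: "); show(object@axis2)
})
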