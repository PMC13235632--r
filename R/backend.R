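# Storage backends for 2D grids. All grid access goes through whole-row /
# column-block reads and writes so that processing never needs more than a
# small constant number of rows or columns resident in memory (the
# out-of-core contract). Accessors are instrumented: when tracking is
# enabled every read/write reports the number of values it materializes.

#' Grid storage backends
#'
#' A \code{GridBackend} stores one real-valued N1 x N2 plane of a 2D data
#' set. Three implementations are provided: \code{MemoryBackend} (an
#' in-memory matrix, for small grids and tests), \code{FileBackend} (a
#' row-major flat binary file, float64 or float32 little-endian), and
#' \code{H5Backend} (a chunked HDF5 dataset). All access is by whole rows
#' or by blocks of contiguous columns.
#'
#' @param x a backend.
#' @param i row index (1-based).
#' @param j first column index of a block (1-based).
#' @param k number of columns in the block.
#' @param value numeric vector (rows) or matrix (column blocks).
#' @name gridBackend
#' @aliases MemoryBackend FileBackend H5Backend
NULL

setClass("GridBackend", representation("VIRTUAL"))

setClass("MemoryBackend", contains = "GridBackend",
         representation(env = "environment"))

setClass("FileBackend", contains = "GridBackend",
         representation(path = "character", n1 = "integer", n2 = "integer",
                        bytes = "integer"))

setClass("H5Backend", contains = "GridBackend",
         representation(path = "character", name = "character",
                        n1 = "integer", n2 = "integer"))

## ---- instrumentation ------------------------------------------------------

.ioTracker <- new.env(parent = emptyenv())
.ioTracker$enabled <- FALSE

.trackerReset <- function() {
  .ioTracker$reads <- 0L
  .ioTracker$writes <- 0L
  .ioTracker$current <- 0
  .ioTracker$peak <- 0
}

.trackIO <- function(n, write = FALSE) {
  if (!.ioTracker$enabled) return(invisible(NULL))
  if (write) .ioTracker$writes <- .ioTracker$writes + 1L
  else .ioTracker$reads <- .ioTracker$reads + 1L
  .ioTracker$current <- .ioTracker$current + n
  if (.ioTracker$current > .ioTracker$peak) .ioTracker$peak <- .ioTracker$current
  invisible(NULL)
}

#' Mark the end of one processing unit (row or column block)
#'
#' Out-of-core loops call this once per iteration, after the buffers of the
#' iteration are dead; the tracker's resident count is reset so the peak
#' reflects the largest footprint of any single iteration.
#' @return invisibly \code{NULL}.
#' @export
noteBufferCycle <- function() {
  if (.ioTracker$enabled) .ioTracker$current <- 0
  invisible(NULL)
}

#' Run an expression with grid-access tracking
#'
#' Instruments every backend read/write while \code{expr} runs and reports
#' the peak number of values resident within any single processing cycle.
#' Used to assert the one-row/one-column memory contract.
#'
#' @param expr expression to evaluate.
#' @return list with \code{result}, \code{peakResident} (values), and the
#'   \code{reads}/\code{writes} operation counts.
#' @examples
#' b <- memoryBackend(matrix(0, 4, 8))
#' withMemoryTracking(readRowValues(b, 2))$peakResident
#' @export
withMemoryTracking <- function(expr) {
  .trackerReset()
  .ioTracker$enabled <- TRUE
  on.exit(.ioTracker$enabled <- FALSE)
  res <- force(expr)
  list(result = res, peakResident = .ioTracker$peak,
       reads = .ioTracker$reads, writes = .ioTracker$writes)
}

## ---- memory backend -------------------------------------------------------

#' @rdname gridBackend
#' @param data numeric matrix for \code{memoryBackend}.
#' @export
memoryBackend <- function(data) {
  stopifnot(is.matrix(data), is.numeric(data))
  e <- new.env(parent = emptyenv())
  e$data <- data
  new("MemoryBackend", env = e)
}

setMethod("backendDims", "MemoryBackend", function(x) dim(x@env$data))

setMethod("readRowValues", "MemoryBackend", function(x, i) {
  .trackIO(ncol(x@env$data))
  x@env$data[i, ]
})

setMethod("writeRowValues", "MemoryBackend", function(x, i, value) {
  .trackIO(length(value), write = TRUE)
  x@env$data[i, ] <- value
  invisible(x)
})

setMethod("readColBlock", "MemoryBackend", function(x, j, k) {
  .trackIO(nrow(x@env$data) * k)
  x@env$data[, j:(j + k - 1L), drop = FALSE]
})

setMethod("writeColBlock", "MemoryBackend", function(x, j, value) {
  .trackIO(length(value), write = TRUE)
  x@env$data[, j:(j + ncol(value) - 1L)] <- value
  invisible(x)
})

## ---- flat-binary file backend --------------------------------------------

# Row-major float little-endian, row i at byte offset (i-1)*n2*bytes.

#' @rdname gridBackend
#' @param path file path.
#' @param n1,n2 grid dimensions (rows, columns).
#' @param bytes 8 for float64 (processing precision) or 4 for float32 (the
#'   documented raw-transient dialect).
#' @param create preallocate the file with zeros.
#' @export
fileBackend <- function(path, n1, n2, bytes = 8L, create = FALSE) {
  n1 <- as.integer(n1); n2 <- as.integer(n2); bytes <- as.integer(bytes)
  stopifnot(bytes %in% c(4L, 8L), n1 >= 1L, n2 >= 1L)
  if (create) {
    con <- file(path, "wb")
    zeros <- numeric(n2)
    for (i in seq_len(n1)) writeBin(zeros, con, size = bytes, endian = "little")
    close(con)
  } else {
    expected <- as.numeric(n1) * n2 * bytes
    if (!file.exists(path))
      stop("flat-binary grid file does not exist: ", path)
    if (file.size(path) != expected)
      stop(sprintf("dimension error: file %s has %.0f bytes, expected %.0f (%d x %d x %d)",
                   path, file.size(path), expected, n1, n2, bytes))
  }
  new("FileBackend", path = path, n1 = n1, n2 = n2, bytes = bytes)
}

setMethod("backendDims", "FileBackend", function(x) c(x@n1, x@n2))

setMethod("readRowValues", "FileBackend", function(x, i) {
  con <- file(x@path, "rb")
  on.exit(close(con))
  seek(con, (i - 1) * as.numeric(x@n2) * x@bytes)
  v <- readBin(con, "numeric", n = x@n2, size = x@bytes, endian = "little")
  .trackIO(x@n2)
  v
})

setMethod("writeRowValues", "FileBackend", function(x, i, value) {
  stopifnot(length(value) == x@n2)
  con <- file(x@path, "r+b")
  on.exit(close(con))
  seek(con, (i - 1) * as.numeric(x@n2) * x@bytes, rw = "write")
  writeBin(as.numeric(value), con, size = x@bytes, endian = "little")
  .trackIO(x@n2, write = TRUE)
  invisible(x)
})

setMethod("readColBlock", "FileBackend", function(x, j, k) {
  con <- file(x@path, "rb")
  on.exit(close(con))
  out <- matrix(0, x@n1, k)
  off0 <- (j - 1) * as.numeric(x@bytes)
  rowBytes <- as.numeric(x@n2) * x@bytes
  for (i in seq_len(x@n1)) {
    seek(con, (i - 1) * rowBytes + off0)
    out[i, ] <- readBin(con, "numeric", n = k, size = x@bytes, endian = "little")
  }
  .trackIO(x@n1 * k)
  out
})

setMethod("writeColBlock", "FileBackend", function(x, j, value) {
  stopifnot(nrow(value) == x@n1)
  con <- file(x@path, "r+b")
  on.exit(close(con))
  off0 <- (j - 1) * as.numeric(x@bytes)
  rowBytes <- as.numeric(x@n2) * x@bytes
  for (i in seq_len(x@n1)) {
    seek(con, (i - 1) * rowBytes + off0, rw = "write")
    writeBin(as.numeric(value[i, ]), con, size = x@bytes, endian = "little")
  }
  .trackIO(length(value), write = TRUE)
  invisible(x)
})

## ---- HDF5 backend ---------------------------------------------------------

# One chunked 2D dataset per plane under /stages/<tag>/<plane>, chunk shape
# (1, N2): chunking aligned with the row pass; column passes read blocks.

#' @rdname gridBackend
#' @param name HDF5 dataset name, e.g. \code{"/stages/raw/r"}.
#' @export
h5Backend <- function(path, name, n1, n2, create = FALSE) {
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (create) {
    if (!file.exists(path)) rhdf5::h5createFile(path)
    parts <- strsplit(gsub("^/+", "", name), "/")[[1]]
    cur <- ""
    for (g in parts[-length(parts)]) {   # create intermediate groups
      cur <- paste0(cur, "/", g)
      fid <- rhdf5::H5Fopen(path)
      exists <- rhdf5::H5Lexists(fid, cur)
      rhdf5::H5Fclose(fid)
      if (!exists) rhdf5::h5createGroup(path, cur)
    }
    rhdf5::h5createDataset(path, name, dims = c(n1, n2),
                           chunk = c(1L, min(n2, 65536L)),
                           storage.mode = "double")
  }
  new("H5Backend", path = path, name = name, n1 = n1, n2 = n2)
}

setMethod("backendDims", "H5Backend", function(x) c(x@n1, x@n2))

setMethod("readRowValues", "H5Backend", function(x, i) {
  v <- as.numeric(rhdf5::h5read(x@path, x@name, index = list(i, NULL)))
  .trackIO(x@n2)
  v
})

setMethod("writeRowValues", "H5Backend", function(x, i, value) {
  stopifnot(length(value) == x@n2)
  rhdf5::h5write(matrix(as.numeric(value), 1L), x@path, x@name,
                 index = list(i, NULL))
  .trackIO(x@n2, write = TRUE)
  invisible(x)
})

setMethod("readColBlock", "H5Backend", function(x, j, k) {
  m <- rhdf5::h5read(x@path, x@name, index = list(NULL, j:(j + k - 1L)))
  .trackIO(x@n1 * k)
  matrix(as.numeric(m), x@n1, k)
})

setMethod("writeColBlock", "H5Backend", function(x, j, value) {
  stopifnot(nrow(value) == x@n1)
  rhdf5::h5write(value, x@path, x@name, index = list(NULL, j:(j + ncol(value) - 1L)))
  .trackIO(length(value), write = TRUE)
  invisible(x)
})
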