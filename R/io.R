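# Dataset I/O. Two documented on-disk layouts:
#
# Flat-binary dialect ("ser-like"): <base>.bin holds one plane, row-major
# float32 or float64 little-endian, N1 x N2; multi-plane data sets use
# <base>_<plane>.bin. A text sidecar <base>.params (key=value, '#' comments)
# carries the acquisition parameters, dtype, stage, plane list and axes.
#
# HDF5 layout: one 2D chunked dataset per plane under /stages/<tag>/<plane>,
# chunk shape (1, N2) aligned with the row pass; metadata as scalar datasets
# under /meta. The layout is self-describing and independent of any vendor
# format.

.SIDE_REQUIRED <- c("magnetic_field", "n_t1", "dt1", "n_t2", "sample_rate_t2")

.writeKv <- function(kv, path) {
  writeLines(paste0(names(kv), " = ", vapply(kv, as.character, "")), path)
}

.readKv <- function(path) {
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- ln[grepl("=", ln, fixed = TRUE)]
  key <- trimws(sub("=.*$", "", ln))
  val <- trimws(sub("^[^=]*=", "", ln))
  stats::setNames(as.list(val), key)
}

.paramsToKv <- function(params) {
  list(magnetic_field = params@magneticField, n_t1 = params@nT1,
       dt1 = params@dt1, n_t2 = params@nT2,
       sample_rate_t2 = params@sampleRateT2,
       f2_low = params@f2Low, f2_high = params@f2High,
       f1_offset = params@f1Offset)
}

.kvToParams <- function(kv, where) {
  missing <- setdiff(.SIDE_REQUIRED, names(kv))
  if (length(missing))
    stop(sprintf("format error in %s: missing required field(s): %s",
                 where, paste(missing, collapse = ", ")))
  num <- function(k, default = NULL) {
    if (!is.null(kv[[k]])) as.numeric(kv[[k]]) else default
  }
  acquisitionParams(num("magnetic_field"), num("n_t1"), num("dt1"),
                    num("n_t2"), num("sample_rate_t2"),
                    f2Low = num("f2_low", 0),
                    f2High = num("f2_high", num("sample_rate_t2") / 2),
                    f1Offset = num("f1_offset", 0))
}

.axisToKv <- function(axis, prefix) {
  kv <- list(axis@kind, axis@nPoints, axis@start, axis@step,
             tolower(axis@descending))
  names(kv) <- paste0(prefix, "_", c("kind", "n", "start", "step", "descending"))
  kv
}

.kvToAxis <- function(kv, prefix, where) {
  g <- function(s) kv[[paste0(prefix, "_", s)]]
  if (is.null(g("kind")))
    stop(sprintf("format error in %s: missing required field: %s_kind",
                 where, prefix))
  axisSpec(g("kind"), as.integer(g("n")), as.numeric(g("start")),
           as.numeric(g("step")), identical(g("descending"), "true"))
}

#' Write a data set to disk
#'
#' @param x a \code{\linkS4class{Dataset2D}}.
#' @param path output path: \code{<base>.params} (or \code{<base>}) for the
#'   flat-binary dialect, \code{<base>.h5} for HDF5.
#' @param format \code{"flat"} or \code{"h5"}; inferred from the extension
#'   by default.
#' @param dtype \code{"float32"} or \code{"float64"} (flat-binary only).
#' @return the path of the metadata file, invisibly.
#' @seealso \code{\link{openDataset}}
#' @export
writeDataset <- function(x, path, format = c("auto", "flat", "h5"),
                         dtype = c("float64", "float32")) {
  format <- match.arg(format)
  dtype <- match.arg(dtype)
  if (format == "auto")
    format <- if (grepl("\\.h5$", path)) "h5" else "flat"
  d <- gridDims(x)
  if (format == "flat") {
    base <- sub("\\.params$", "", path)
    bytes <- if (dtype == "float32") 4L else 8L
    multi <- length(x@planes) > 1L
    for (p in names(x@planes)) {
      bp <- if (multi) sprintf("%s_%s.bin", base, p) else paste0(base, ".bin")
      out <- fileBackend(bp, d[1], d[2], bytes = bytes, create = TRUE)
      for (i in seq_len(d[1])) {
        writeRowValues(out, i, readRowValues(x@planes[[p]], i))
        noteBufferCycle()
      }
    }
    kv <- c(.paramsToKv(x@params),
            list(dtype = dtype, endian = "little", stage = x@stage,
                 planes = paste(names(x@planes), collapse = ",")),
            .axisToKv(x@axis1, "axis1"), .axisToKv(x@axis2, "axis2"))
    meta <- paste0(base, ".params")
    .writeKv(kv, meta)
    invisible(meta)
  } else {
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5createGroup(path, "stages")
    rhdf5::h5createGroup(path, file.path("stages", x@stage))
    for (p in names(x@planes)) {
      name <- sprintf("/stages/%s/%s", x@stage, p)
      out <- h5Backend(path, name, d[1], d[2], create = TRUE)
      for (i in seq_len(d[1])) {
        writeRowValues(out, i, readRowValues(x@planes[[p]], i))
        noteBufferCycle()
      }
    }
    kv <- c(.paramsToKv(x@params),
            list(stage = x@stage, planes = paste(names(x@planes), collapse = ",")),
            .axisToKv(x@axis1, "axis1"), .axisToKv(x@axis2, "axis2"))
    rhdf5::h5createGroup(path, "meta")
    for (k in names(kv))
      rhdf5::h5write(as.character(kv[[k]]), path, paste0("meta/", k))
    rhdf5::h5closeAll()
    invisible(path)
  }
}

#' Open a stored data set lazily
#'
#' Opens a data set written in the documented HDF5 layout or the flat-binary
#' dialect. Only metadata is read; grid values stay on disk and are accessed
#' row- or column-wise through the returned
#' \code{\linkS4class{Dataset2D}}'s accessors (no full-grid load).
#'
#' @param path path to \code{<base>.params}, \code{<base>.bin}, or
#'   \code{<base>.h5}.
#' @return a lazily file-backed \code{Dataset2D}.
#' @examples
#' p <- acquisitionParams(15, 4, 2e-6, 8, 1e6)
#' d <- emptyDataset2d(4, 8,
#'   axisSpec("time", 4, 0, 2e-6), axisSpec("time", 8, 0, 1e-6),
#'   "raw", p, backing = "memory")
#' f <- file.path(tempdir(), "toy")
#' writeDataset(d, f)
#' openDataset(file.path(tempdir(), "toy.params"))
#' @export
openDataset <- function(path) {
  if (grepl("\\.h5$", path)) return(.openH5(path))
  base <- sub("\\.(params|bin)$", "", path)
  meta <- paste0(base, ".params")
  if (!file.exists(meta))
    stop("format error: sidecar parameter file not found: ", meta)
  kv <- .readKv(meta)
  params <- .kvToParams(kv, meta)
  dtype <- if (!is.null(kv$dtype)) kv$dtype else "float32"
  if (!dtype %in% c("float32", "float64"))
    stop("format error in ", meta, ": unsupported dtype: ", dtype)
  bytes <- if (dtype == "float32") 4L else 8L
  stage <- if (!is.null(kv$stage)) kv$stage else "raw"
  planes <- if (!is.null(kv$planes)) strsplit(kv$planes, ",")[[1]] else "r"
  if (!is.null(kv$axis1_kind)) {
    axis1 <- .kvToAxis(kv, "axis1", meta)
    axis2 <- .kvToAxis(kv, "axis2", meta)
  } else {
    axis1 <- axisSpec("time", params@nT1, 0, params@dt1)
    axis2 <- axisSpec("time", params@nT2, 0, 1 / params@sampleRateT2)
  }
  n1 <- axis1@nPoints; n2 <- axis2@nPoints
  pl <- lapply(planes, function(p) {
    bp <- if (length(planes) > 1L) sprintf("%s_%s.bin", base, p)
          else paste0(base, ".bin")
    fileBackend(bp, n1, n2, bytes = bytes)   # validates stored size vs metadata
  })
  names(pl) <- planes
  dataset2d(pl, axis1, axis2, stage, params,
            provenance = list(source = meta))
}

.openH5 <- function(path) {
  if (!file.exists(path)) stop("format error: file not found: ", path)
  idx <- rhdf5::h5ls(path)
  readMeta <- function(k) {
    if (!any(idx$group == "/meta" & idx$name == k)) return(NULL)
    as.character(rhdf5::h5read(path, paste0("meta/", k)))
  }
  kv <- list()
  for (k in idx$name[idx$group == "/meta"]) kv[[k]] <- readMeta(k)
  params <- .kvToParams(kv, path)
  stage <- if (!is.null(kv$stage)) kv$stage else "raw"
  planes <- if (!is.null(kv$planes)) strsplit(kv$planes, ",")[[1]] else "r"
  axis1 <- .kvToAxis(kv, "axis1", path)
  axis2 <- .kvToAxis(kv, "axis2", path)
  stored <- idx[idx$group == paste0("/stages/", stage), , drop = FALSE]
  pl <- lapply(planes, function(p) {
    name <- sprintf("/stages/%s/%s", stage, p)
    row <- stored[stored$name == p, , drop = FALSE]
    if (!nrow(row))
      stop("format error in ", path, ": missing plane dataset ", name)
    dims <- as.integer(strsplit(row$dim, " x ")[[1]])
    if (dims[1] != axis1@nPoints || dims[2] != axis2@nPoints)
      stop(sprintf("dimension error in %s: stored grid is %d x %d but metadata declares %d x %d",
                   path, dims[1], dims[2], axis1@nPoints, axis2@nPoints))
    h5Backend(path, name, dims[1], dims[2])
  })
  names(pl) <- planes
  rhdf5::h5closeAll()
  dataset2d(pl, axis1, axis2, stage, params, provenance = list(source = path))
}

#' Read and write scans as CSV
#'
#' Two-column CSV (\code{axis}, \code{intensity}); complex scans gain an
#' \code{intensity_imag} column.
#'
#' @param x a \code{\linkS4class{Scan}}.
#' @param path CSV path.
#' @return \code{writeScanCsv}: the path invisibly; \code{readScanCsv}: a
#'   data frame.
#' @export
writeScanCsv <- function(x, path) {
  df <- data.frame(axis = axisValues(x@axis))
  if (is.complex(x@values)) {
    df$intensity <- Re(x@values)
    df$intensity_imag <- Im(x@values)
  } else df$intensity <- x@values
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScanCsv
#' @export
readScanCsv <- function(path) utils::read.csv(path)
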