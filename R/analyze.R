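# Scan extraction and spectral analysis: noise and SNR, resolving power by
# FWHM interpolation, fragment/precursor ion scan extraction, the
# autocorrelation line, scan summing, and 2D peak picking with independent
# parabolic centroiding in each dimension.

#' Noise estimate from an empty spectral segment
#'
#' The noise level is the mean of the absolute intensity over an empty
#' segment of the spectrum close to the peaks of interest.
#'
#' @slot level noise level, intensity units (>= 0).
#' @slot region (start, end) indices of the segment used.
#' @export
setClass("NoiseEstimate",
         representation(level = "numeric", region = "integer"))

setValidity("NoiseEstimate", function(object) {
  if (object@level < 0) return("level must be >= 0")
  if (length(object@region) != 2L || object@region[1] > object@region[2])
    return("region must be (start, end) with start <= end")
  TRUE
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: level %.6g over bins [%d, %d]\n",
              object@level, object@region[1], object@region[2]))
})

#' Noise level of a scan
#'
#' Mean absolute intensity over the given (peak-free) segment.
#'
#' @param scan a \code{\linkS4class{Scan}}.
#' @param region integer (start, end) indices, length >= 8 points, within
#'   the scan; \code{NULL} picks the lowest-decile window automatically
#'   (see \code{\link{autoNoiseRegion}}).
#' @return a \code{\linkS4class{NoiseEstimate}}.
#' @export
noiseLevel <- function(scan, region = NULL) {
  v <- if (is(scan, "Scan")) scan@values else scan
  if (is.complex(v)) v <- Re(v)
  if (is.null(region)) region <- autoNoiseRegion(v)
  region <- as.integer(region)
  if (length(region) != 2L || region[1] < 1L || region[2] > length(v))
    stop("validation error: region must be (start, end) within the scan")
  if (region[2] - region[1] + 1L < 8L)
    stop("validation error: noise region must span at least 8 points")
  new("NoiseEstimate", level = mean(abs(v[region[1]:region[2]])),
      region = region)
}

#' Automatic empty-segment selection
#'
#' Splits the scan into windows and returns the indices of the window with
#' the lowest mean absolute intensity (the lowest-decile heuristic standing
#' in for a manually chosen empty segment).
#'
#' @param v numeric vector or \code{Scan}.
#' @param nWindows number of candidate windows.
#' @return integer (start, end).
#' @export
autoNoiseRegion <- function(v, nWindows = 16L) {
  if (is(v, "Scan")) v <- v@values
  if (is.complex(v)) v <- Re(v)
  n <- length(v)
  nWindows <- max(1L, min(as.integer(nWindows), n %/% 8L))
  bounds <- floor(seq(0L, n, length.out = nWindows + 1L))
  means <- vapply(seq_len(nWindows), function(w)
    mean(abs(v[(bounds[w] + 1L):bounds[w + 1L]])), 0)
  w <- which.min(means)
  c(bounds[w] + 1L, bounds[w + 1L])
}

#' Signal-to-noise ratio of a peak
#'
#' Peak intensity divided by the noise level. A zero noise level yields
#' \code{Inf}.
#'
#' @param scan a \code{\linkS4class{Scan}}.
#' @param peakIndex 1-based bin of the peak.
#' @param noise a \code{\linkS4class{NoiseEstimate}}, numeric level, or
#'   \code{NULL} for the automatic estimate.
#' @return dimensionless SNR.
#' @export
snr <- function(scan, peakIndex, noise = NULL) {
  v <- if (is(scan, "Scan")) scan@values else scan
  if (is.complex(v)) v <- Re(v)
  level <- if (is.null(noise)) noiseLevel(scan)@level
           else if (is(noise, "NoiseEstimate")) noise@level
           else as.numeric(noise)
  if (level == 0) return(Inf)
  v[peakIndex] / level
}

#' Resolving power from the FWHM
#'
#' The full width at half maximum is found by linear interpolation of the
#' half-maximum crossings on the frequency axis; the resolving power is
#' f_peak / FWHM, which equals m/Dm since m is locally proportional to 1/f.
#' For indirect-dimension scans whose axis holds modulation frequencies,
#' \code{fOffset} restores the absolute cyclotron frequency.
#'
#' @param scan a real frequency-axis \code{\linkS4class{Scan}}.
#' @param peakIndex apex bin.
#' @param fOffset added to the axis frequency of the apex (Hz).
#' @return resolving power, or \code{NA} when the half-maximum crossings
#'   cannot be resolved (peak overlap or truncation).
#' @export
resolvingPower <- function(scan, peakIndex, fOffset = 0) {
  v <- if (is(scan, "Scan")) scan@values else scan
  if (is.complex(v)) v <- Re(v)
  ax <- if (is(scan, "Scan")) scan@axis else NULL
  x <- if (is.null(ax)) seq_along(v) else axisValues(ax)
  half <- v[peakIndex] / 2
  if (half <= 0) return(NA_real_)
  # walk down each flank until the first point below half maximum; a rise
  # before the crossing means overlap with a neighboring peak
  i <- peakIndex
  while (i > 1L && v[i - 1L] >= half) {
    if (v[i - 1L] > v[i]) return(NA_real_)
    i <- i - 1L
  }
  if (i == 1L) return(NA_real_)                 # truncated at the edge
  xl <- x[i - 1L] + (x[i] - x[i - 1L]) * (half - v[i - 1L]) / (v[i] - v[i - 1L])
  j <- peakIndex
  n <- length(v)
  while (j < n && v[j + 1L] >= half) {
    if (v[j + 1L] > v[j]) return(NA_real_)
    j <- j + 1L
  }
  if (j == n) return(NA_real_)
  xr <- x[j] + (x[j + 1L] - x[j]) * (half - v[j]) / (v[j + 1L] - v[j])
  fwhm <- xr - xl
  if (!is.finite(fwhm) || fwhm <= 0) return(NA_real_)
  if (!is.null(ax) && ax@kind == "mz") x[peakIndex] / fwhm
  else (x[peakIndex] + fOffset) / fwhm
}

## ---- scan extraction ------------------------------------------------------

.nearestIndex <- function(values, target) which.min(abs(values - target))

.precursorRowIndex <- function(d, precursorMz, cal) {
  nu1 <- mzToFreq(cal, precursorMz) - d@params@f1Offset
  f1 <- axisValues(d@axis1)
  if (nu1 < f1[1] - d@axis1@step / 2 || nu1 > f1[length(f1)] + d@axis1@step / 2)
    stop(sprintf("range error: precursor m/z %.4f (modulation frequency %.1f Hz) outside the F1 axis",
                 precursorMz, nu1))
  .nearestIndex(f1, nu1)
}

.fragmentColIndex <- function(d, fragmentMz, cal) {
  f <- mzToFreq(cal, fragmentMz)
  f2 <- axisValues(d@axis2)
  if (f < f2[1] - d@axis2@step / 2 || f > f2[length(f2)] + d@axis2@step / 2)
    stop(sprintf("range error: fragment m/z %.4f (frequency %.1f Hz) outside the F2 axis",
                 fragmentMz, f))
  .nearestIndex(f2, f)
}

#' Extract 1D scans from a fully transformed 2D spectrum
#'
#' \code{extractFragmentScan} returns the row nearest a precursor m/z (an
#' MS/MS-like fragment ion scan); \code{extractPrecursorScan} the column
#' nearest a fragment m/z (all precursors producing that fragment);
#' \code{autocorrelationLine} the diagonal where precursor m/z equals
#' fragment m/z (unfragmented precursors). Axes stay in frequency; use
#' \code{\link{scanMzValues}} for the m/z display values.
#'
#' @param d a \code{fully-transformed-*} \code{\linkS4class{Dataset2D}}.
#' @param precursorMz,fragmentMz target m/z, Th.
#' @param calF1,calF2 \code{\linkS4class{CalibrationQuadratic}}s for the
#'   precursor and fragment axes (mapping absolute cyclotron frequency to
#'   m/z; the F1 axis offset is taken from the acquisition parameters).
#' @return a \code{\linkS4class{Scan}}.
#' @export
extractFragmentScan <- function(d, precursorMz, calF1, calF2 = calF1) {
  .checkTransformed(d)
  i <- .precursorRowIndex(d, precursorMz, calF1)
  s <- getRow(d, i)
  s@origin <- sprintf("fragment-ion-scan precursor_mz=%.5f (row %d)",
                      precursorMz, i)
  s
}

#' @rdname extractFragmentScan
#' @export
extractPrecursorScan <- function(d, fragmentMz, calF1, calF2 = calF1) {
  .checkTransformed(d)
  j <- .fragmentColIndex(d, fragmentMz, calF2)
  s <- getCol(d, j)
  s@origin <- sprintf("precursor-ion-scan fragment_mz=%.5f (column %d)",
                      fragmentMz, j)
  s
}

#' @rdname extractFragmentScan
#' @export
autocorrelationLine <- function(d, calF1, calF2 = calF1) {
  .checkTransformed(d)
  f2 <- axisValues(d@axis2)
  f1 <- axisValues(d@axis1)
  n2 <- length(f2)
  out <- numeric(n2)
  for (j in seq_len(n2)) {
    mz <- freqToMz(calF2, max(f2[j], calF2@fRange[1] * 1e-6))
    nu1 <- mzToFreq(calF1, mz) - d@params@f1Offset
    i <- .nearestIndex(f1, nu1)
    if (abs(f1[i] - nu1) <= d@axis1@step)
      out[j] <- scanValues(getCol(d, j))[i]
    noteBufferCycle()
  }
  scan1d(out, d@axis2, "autocorrelation")
}

.checkTransformed <- function(d) {
  if (!grepl("^fully-transformed", d@stage))
    stop("stage error: expected a fully transformed data set, got stage ",
         d@stage)
}

#' m/z display values of a frequency-axis scan
#'
#' @param scan a frequency-axis \code{\linkS4class{Scan}}.
#' @param cal a \code{\linkS4class{CalibrationQuadratic}}.
#' @param fOffset offset added to axis frequencies before conversion
#'   (indirect dimension), Hz.
#' @return numeric m/z values (descending as frequency ascends).
#' @export
scanMzValues <- function(scan, cal, fOffset = 0) {
  f <- axisValues(scan@axis) + fOffset
  ok <- f > 0
  out <- rep(NA_real_, length(f))
  out[ok] <- freqToMz(cal, f[ok])
  out
}

#' Sum adjacent scans of a 2D spectrum
#'
#' Elementwise sum of a contiguous range of rows (fragment ion scans, e.g.
#' to cover a precursor isotopic distribution) or columns.
#'
#' @param d a \code{\linkS4class{Dataset2D}}.
#' @param rows,cols 1-based index range (give exactly one).
#' @return a \code{\linkS4class{Scan}}.
#' @export
sumScans <- function(d, rows = NULL, cols = NULL) {
  if (is.null(rows) == is.null(cols))
    stop("validation error: give exactly one of rows or cols")
  idx <- if (is.null(rows)) cols else rows
  if (!length(idx)) stop("validation error: empty range")
  get <- if (is.null(rows)) getCol else getRow
  acc <- scanValues(get(d, idx[1]))
  for (i in idx[-1]) {
    acc <- acc + scanValues(get(d, i))
    noteBufferCycle()
  }
  ax <- if (is.null(rows)) d@axis1 else d@axis2
  scan1d(acc, ax, sprintf("sum of %d %s", length(idx),
                          if (is.null(rows)) "columns" else "rows"))
}

## ---- 2D peak picking ------------------------------------------------------

.parabolicDelta <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (den >= 0) return(NA_real_)   # not a concave apex
  d <- 0.5 * (ym - yp) / den
  if (!is.finite(d) || abs(d) > 0.5) NA_real_ else d
}

#' Global noise level of a 2D spectrum
#'
#' Samples rows evenly, splits each into windows, and averages the lowest
#' decile of the window mean absolute intensities.
#'
#' @param d a \code{\linkS4class{Dataset2D}}.
#' @param maxRows number of rows to sample.
#' @return noise level (intensity units).
#' @export
noiseLevel2d <- function(d, maxRows = 32L) {
  n <- gridDims(d)
  rows <- unique(round(seq(1L, n[1], length.out = min(maxRows, n[1]))))
  wm <- c()
  for (i in rows) {
    v <- abs(scanValues(getRow(d, i)))
    nw <- max(1L, min(16L, length(v) %/% 8L))
    bounds <- floor(seq(0L, length(v), length.out = nw + 1L))
    wm <- c(wm, vapply(seq_len(nw), function(w)
      mean(v[(bounds[w] + 1L):bounds[w + 1L]]), 0))
    noteBufferCycle()
  }
  lowest <- sort(wm)[seq_len(max(1L, ceiling(length(wm) / 10)))]
  mean(lowest)
}

#' Two-dimensional peak picking and centroiding
#'
#' Finds local maxima over the 8-neighborhood exceeding
#' \code{thresholdMultiple} times the noise level, then centroids each peak
#' independently in both dimensions by 3-point parabolic interpolation
#' through the apex (falling back to the apex bin when a neighbor is
#' negative or the parabola is degenerate). Per-dimension SNR and resolving
#' power are measured on the peak's row and column scans. The grid is
#' streamed three rows at a time.
#'
#' @param d a \code{fully-transformed-*} \code{\linkS4class{Dataset2D}}.
#' @param thresholdMultiple detection threshold in noise units (>= 1).
#' @param noise noise level; \code{NULL} for \code{\link{noiseLevel2d}}.
#' @param calF1,calF2 optional calibrations to assign precursor and
#'   fragment m/z.
#' @param measureScans also measure per-dimension SNR and resolving power
#'   (extracts one row and one column per peak).
#' @return data frame with one row per peak: f1_hz, f2_hz (centroided),
#'   intensity, row, col, centroided_f1/f2, and when calibrated
#'   precursor_mz, fragment_mz, and when measured snr_f1, snr_f2, rp_f1,
#'   rp_f2. Ordered by (precursor m/z, fragment m/z) when calibrated, else
#'   by (f1, f2); equal-intensity neighboring maxima keep the lower index.
#' @export
pickPeaks2d <- function(d, thresholdMultiple = 3, noise = NULL,
                        calF1 = NULL, calF2 = calF1, measureScans = TRUE) {
  .checkTransformed(d)
  if (thresholdMultiple < 1) stop("validation error: thresholdMultiple must be >= 1")
  n <- gridDims(d)
  if (is.null(noise)) noise <- noiseLevel2d(d)
  thr <- thresholdMultiple * noise
  f1 <- axisValues(d@axis1); f2 <- axisValues(d@axis2)
  peaks <- list()
  if (n[1] >= 3L && n[2] >= 3L) {
  prev <- scanValues(getRow(d, 1L))
  cur <- scanValues(getRow(d, 2L))
  for (i in seq_len(n[1] - 2L) + 1L) {
    nxt <- scanValues(getRow(d, i + 1L))
    for (j in seq_len(n[2] - 2L) + 1L) {
      y0 <- cur[j]
      if (y0 <= thr) next
      # 8-neighborhood maximum; on ties the lower-index point wins, so
      # require strict > over earlier neighbors and >= over later ones
      earlier <- c(prev[(j - 1L):(j + 1L)], cur[j - 1L])
      later <- c(cur[j + 1L], nxt[(j - 1L):(j + 1L)])
      if (y0 <= max(earlier) || y0 < max(later)) next
      d1 <- .parabolicDelta(prev[j], y0, nxt[j])
      d2 <- .parabolicDelta(cur[j - 1L], y0, cur[j + 1L])
      c1 <- !is.na(d1) && prev[j] > 0 && nxt[j] > 0
      c2 <- !is.na(d2) && cur[j - 1L] > 0 && cur[j + 1L] > 0
      peaks[[length(peaks) + 1L]] <- data.frame(
        row = i, col = j, intensity = y0,
        f1_hz = f1[i] + if (c1) d1 * d@axis1@step else 0,
        f2_hz = f2[j] + if (c2) d2 * d@axis2@step else 0,
        centroided_f1 = c1, centroided_f2 = c2)
    }
    prev <- cur; cur <- nxt
    noteBufferCycle()
  }
  }
  if (!length(peaks)) {
    out <- data.frame(row = integer(0), col = integer(0),
                      intensity = numeric(0), f1_hz = numeric(0),
                      f2_hz = numeric(0), centroided_f1 = logical(0),
                      centroided_f2 = logical(0))
    return(out)
  }
  out <- do.call(rbind, peaks)
  if (measureScans) {
    m <- nrow(out)
    out$snr_f1 <- out$snr_f2 <- out$rp_f1 <- out$rp_f2 <- NA_real_
    for (k in seq_len(m)) {
      rowScan <- getRow(d, out$row[k])
      colScan <- getCol(d, out$col[k])
      # per-dimension SNR against each scan's own empty segment
      out$snr_f2[k] <- snr(rowScan, out$col[k])
      out$snr_f1[k] <- snr(colScan, out$row[k])
      out$rp_f2[k] <- resolvingPower(rowScan, out$col[k])
      out$rp_f1[k] <- resolvingPower(colScan, out$row[k],
                                     fOffset = d@params@f1Offset)
      noteBufferCycle()
    }
  }
  if (!is.null(calF1)) {
    out$precursor_mz <- freqToMz(calF1, out$f1_hz + d@params@f1Offset)
    out$fragment_mz <- freqToMz(calF2, pmax(out$f2_hz, 1e-9))
    out <- out[order(out$precursor_mz, out$fragment_mz), , drop = FALSE]
  } else {
    out <- out[order(out$f1_hz, out$f2_hz), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a peak table as CSV
#'
#' Columns (when present): precursor_mz, fragment_mz, intensity, snr_f1,
#' snr_f2, rp_f1, rp_f2, plus the centroided frequencies.
#'
#' @param peaks data frame from \code{\link{pickPeaks2d}}.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
writePeaksCsv <- function(peaks, path) {
  lead <- intersect(c("precursor_mz", "fragment_mz", "intensity",
                      "snr_f1", "snr_f2", "rp_f1", "rp_f2"), names(peaks))
  rest <- setdiff(names(peaks), lead)
  utils::write.csv(peaks[, c(lead, rest), drop = FALSE], path,
                   row.names = FALSE)
  invisible(path)
}
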