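# Fourier processing: zerofilling, the real-to-complex transforms along each
# dimension, phase correction (quadratic in F2, linear in F1), and the
# two-pass out-of-core pipeline producing absorption- or magnitude-mode 2D
# spectra.
#
# Sign conventions: the DFT is X(f) = sum_t x(t) exp(-2 pi i f t) (stats::fft),
# so a signal cos(2 pi f0 t + phi) puts a complex amplitude with phase +phi at
# the +f0 bin; phase correction multiplies by exp(-i phi_model(f)).

#' Zerofill a time-domain scan
#'
#' Appends zeros, doubling the length once per fill: n fills multiply the
#' length by 2^n. Zerofilling before the FT interpolates the frequency axis
#' without adding information.
#'
#' @param scan a time-domain \code{\linkS4class{Scan}}.
#' @param nFills number of successive doublings (>= 0).
#' @return the zerofilled \code{Scan} (axis extended at the same step).
#' @examples
#' s <- scan1d(rnorm(4096), axisSpec("time", 4096, 0, 2e-6))
#' length(scanValues(zerofill(s, 2)))  # 16384
#' @export
zerofill <- function(scan, nFills) {
  nFills <- as.integer(nFills)
  if (nFills < 0L) stop("validation error: nFills must be >= 0")
  if (nFills == 0L) return(scan)
  n <- length(scan@values)
  n2 <- n * 2L^nFills
  v <- c(scan@values, rep(if (is.complex(scan@values)) 0+0i else 0, n2 - n))
  ax <- axisSpec(scan@axis@kind, n2, scan@axis@start, scan@axis@step,
                 scan@axis@descending)
  scan1d(v, ax, scan@origin)
}

#' Frequency-domain point spacing
#'
#' The spacing of frequency-domain points for a dwell time \code{dt} and a
#' spectrum of \code{nFreqPoints} points covering the Nyquist band:
#' (1/(2 dt)) / nFreqPoints. For the indirect dimension dt is the t1
#' increment; e.g. dt = 2 us with 8192 points gives 30.5 Hz.
#'
#' @param dt sampling interval, seconds.
#' @param nFreqPoints number of frequency-domain points.
#' @return spacing in Hz.
#' @export
axisPointSpacing <- function(dt, nFreqPoints) {
  if (dt <= 0) stop("validation error: dt must be > 0")
  if (nFreqPoints < 1) stop("validation error: nFreqPoints must be >= 1")
  (1 / (2 * dt)) / nFreqPoints
}

.freqAxisFromTime <- function(axis) {
  n <- axis@nPoints
  sr <- 1 / axis@step
  axisSpec("frequency", n %/% 2L, 0, sr / n, descending = FALSE)
}

#' Fourier transform of the direct (fragment, F2) dimension
#'
#' Real-to-complex DFT of one transient; the positive-frequency half
#' spectrum over [0, Nyquist) with n/2 points is returned on a Hz axis.
#'
#' @param transient a real time-domain \code{\linkS4class{Scan}}.
#' @return a complex frequency-domain \code{Scan}.
#' @export
ftF2 <- function(transient) {
  if (transient@axis@kind != "time")
    stop("stage error: ftF2 expects a time-domain scan")
  if (is.complex(transient@values))
    stop("stage error: ftF2 expects real input")
  X <- stats::fft(transient@values)
  n <- length(X)
  scan1d(X[seq_len(n %/% 2L)], .freqAxisFromTime(transient@axis),
         transient@origin)
}

#' Fourier transform of the indirect (precursor, F1) dimension
#'
#' Identical real-to-complex transform applied to a column assembled from
#' the F2-processed rows at one fragment frequency; the t1-domain values
#' are real (amplitude modulation, no phase cycling).
#'
#' @param column a real t1-domain \code{\linkS4class{Scan}}.
#' @return a complex frequency-domain \code{Scan} over the indirect
#'   bandwidth.
#' @export
ftF1 <- function(column) {
  if (column@axis@kind != "time")
    stop("stage error: ftF1 expects a t1-domain scan")
  if (is.complex(column@values))
    stop("stage error: ftF1 expects real input (amplitude-modulated t1 data)")
  X <- stats::fft(column@values)
  n <- length(X)
  scan1d(X[seq_len(n %/% 2L)], .freqAxisFromTime(column@axis), column@origin)
}

.phaseApply <- function(spectrum, phi) {
  scan1d(spectrum@values * exp(-1i * phi), spectrum@axis, spectrum@origin)
}

#' Phase correction
#'
#' Multiplies each frequency-domain point at frequency f by
#' \code{exp(-1i * (a0 + a1 f + a2 f^2))} (\code{phaseF2}, quadratic,
#' fragment dimension) or \code{exp(-1i * (b0 + b1 f))} (\code{phaseF1},
#' linear, precursor dimension). The modulus is preserved pointwise. The
#' frequency used is the absolute detected frequency in Hz taken from the
#' scan's axis, not the bin index.
#'
#' @param spectrum a complex frequency-domain \code{\linkS4class{Scan}}.
#' @param phase a \code{\linkS4class{PhaseFunction2D}}.
#' @param flipSign multiply by \code{exp(+i phi)} instead (for data generated
#'   under the opposite convention).
#' @return the phased complex \code{Scan}.
#' @export
phaseF2 <- function(spectrum, phase, flipSign = FALSE) {
  if (spectrum@axis@kind != "frequency")
    stop("stage error: phase correction expects a frequency-domain scan")
  f <- axisValues(spectrum@axis)
  phi <- phase@a0 + phase@a1 * f + phase@a2 * f^2
  .phaseApply(spectrum, if (flipSign) -phi else phi)
}

#' @rdname phaseF2
#' @export
phaseF1 <- function(spectrum, phase, flipSign = FALSE) {
  if (spectrum@axis@kind != "frequency")
    stop("stage error: phase correction expects a frequency-domain scan")
  f <- axisValues(spectrum@axis)
  phi <- phase@b0 + phase@b1 * f
  .phaseApply(spectrum, if (flipSign) -phi else phi)
}

## ---- two-pass out-of-core pipeline ---------------------------------------

.colBlockWidth <- function(n1, nf2, nf1, nPlanes) {
  # Keep one column-pass iteration's footprint (input columns from nPlanes
  # planes + output columns) within ~4 rows'/columns' worth of values.
  per <- n1 * nPlanes + nf1
  max(1L, min(nf2, as.integer(floor(4 * max(n1, nf2, nf1) / per))))
}

#' Full 2D processing: absorption and magnitude mode
#'
#' The two-pass out-of-core pipeline. Row pass (per transient): apodize,
#' zerofill, F2 transform, quadratic F2 phase correction; the complex result
#' is stored as two real planes. Column pass (per fragment-frequency
#' column): optional AR baseline correction of the initial t1 points,
#' optional apodization/zerofill, F1 transform. In absorption mode the F1
#' linear phase correction is applied to the transformed columns of the
#' phased F2 real plane and the real part is kept. In magnitude mode both F2
#' quadrature planes are carried through the F1 transform and the
#' hypercomplex modulus sqrt(rr^2 + ri^2 + ir^2 + ii^2) is taken, which is
#' invariant under any phase coefficients. No step ever holds more than a
#' few rows or column blocks in memory.
#'
#' @param raw a \code{raw}-stage \code{\linkS4class{Dataset2D}}.
#' @param phase a \code{\linkS4class{PhaseFunction2D}}.
#' @param apodF2,apodF1 \code{\linkS4class{ApodizationSpec}}s per dimension.
#' @param zerofillF2,zerofillF1 fills (doublings) per dimension.
#' @param baselineOrder AR model order for precursor-scan baseline
#'   correction: \code{0} disables, \code{"auto"} chooses from the peak
#'   count, or an integer order.
#' @param baselineNReplace number of initial t1 points to recalculate.
#' @param backing \code{"file"} or \code{"memory"} for intermediate planes.
#' @param dir scratch directory for file-backed planes.
#' @return a \code{fully-transformed-*} stage \code{Dataset2D} with one real
#'   plane (absorption: phased real part, may be negative; magnitude:
#'   nonnegative modulus).
#' @examples
#' \donttest{
#' cfg <- simConfig(acquisitionParams(15, 32, 2e-6, 256, 1e6),
#'                  precursors = list(precursorSpec(700, fragments = list(
#'                    c(mz = 350, charge = 1, efficiency = 0.5)))))
#' sim <- generateDataset2d(cfg)
#' abs2d <- absorption2d(sim$dataset, phaseFunction2d())
#' }
#' @export
absorption2d <- function(raw, phase,
                         apodF2 = apodizationSpec("kv_asymmetric_sqrt_fall"),
                         apodF1 = apodizationSpec("none"),
                         zerofillF2 = 0L, zerofillF1 = 0L,
                         baselineOrder = 0L, baselineNReplace = 0L,
                         backing = "file", dir = tempdir()) {
  .process2d(raw, "absorption", phase, apodF2, apodF1, zerofillF2, zerofillF1,
             baselineOrder, baselineNReplace, backing, dir)
}

#' @rdname absorption2d
#' @export
magnitude2d <- function(raw, phase = phaseFunction2d(),
                        apodF2 = apodizationSpec("sine_bell"),
                        apodF1 = apodizationSpec("none"),
                        zerofillF2 = 0L, zerofillF1 = 0L,
                        baselineOrder = 0L, baselineNReplace = 0L,
                        backing = "file", dir = tempdir()) {
  .process2d(raw, "magnitude", phase, apodF2, apodF1, zerofillF2, zerofillF1,
             baselineOrder, baselineNReplace, backing, dir)
}

.process2d <- function(raw, mode, phase, apodF2, apodF1,
                       zerofillF2, zerofillF1, baselineOrder,
                       baselineNReplace, backing, dir) {
  if (raw@stage != "raw")
    stop("stage error: processing expects a raw-stage data set, got ",
         raw@stage)
  d <- gridDims(raw)
  n1 <- d[1]; n2 <- d[2]
  n2zf <- n2 * 2L^as.integer(zerofillF2)
  nf2 <- n2zf %/% 2L
  f2axis <- axisSpec("frequency", nf2, 0, (1 / raw@axis2@step) / n2zf)

  ## Row pass: apodize + zerofill + FT + quadratic phase per transient.
  stagePlanes <- c("r", "i")
  stage <- emptyDataset2d(n1, nf2, raw@axis1, f2axis, "f2-transformed",
                          raw@params, planes = stagePlanes, backing = backing,
                          dir = dir)
  for (i in seq_len(n1)) {
    tr <- getRow(raw, i)
    tr <- applyApodization(tr, apodF2)
    tr <- zerofill(tr, zerofillF2)
    sp <- ftF2(tr)
    # the modulus is phase-invariant, so magnitude mode skips the phase
    # multiply entirely (identical output for any coefficients, to the bit)
    if (mode == "absorption") sp <- phaseF2(sp, phase)
    putRow(stage, i, sp@values)
    noteBufferCycle()
  }

  ## Column pass: per fragment-frequency column, optional baseline
  ## correction, F1 transform, linear phase / hypercomplex modulus.
  n1zf <- n1 * 2L^as.integer(zerofillF1)
  nf1 <- n1zf %/% 2L
  f1axis <- axisSpec("frequency", nf1, 0, (1 / raw@axis1@step) / n1zf)
  t1axis <- raw@axis1
  outStage <- paste0("fully-transformed-", mode)
  out <- emptyDataset2d(nf1, nf2, f1axis, f2axis, outStage, raw@params,
                        planes = "r", backing = backing, dir = dir)
  prov <- list(mode = mode, phase = phase, apodF2 = apodF2@kind,
               apodF1 = apodF1@kind, zerofillF2 = zerofillF2,
               zerofillF1 = zerofillF1, baselineOrder = baselineOrder,
               baselineNReplace = baselineNReplace)
  out@provenance <- prov

  baselineOn <- (is.character(baselineOrder) || baselineOrder > 0) &&
    baselineNReplace > 0L
  processCol <- function(v) {
    s <- scan1d(v, t1axis)
    if (baselineOn)
      s <- correctScanBaseline(s, order = baselineOrder,
                               nReplace = baselineNReplace)
    s <- applyApodization(s, apodF1)
    s <- zerofill(s, zerofillF1)
    ftF1(s)
  }

  bw <- .colBlockWidth(n1, nf2, nf1, if (mode == "magnitude") 2L else 1L)
  j <- 1L
  while (j <= nf2) {
    k <- min(bw, nf2 - j + 1L)
    blockR <- readColBlock(stage@planes[["r"]], j, k)
    if (mode == "magnitude")
      blockI <- readColBlock(stage@planes[["i"]], j, k)
    outBlock <- matrix(0, nf1, k)
    for (jj in seq_len(k)) {
      SR <- processCol(blockR[, jj])
      if (mode == "absorption") {
        outBlock[, jj] <- Re(phaseF1(SR, phase)@values)
      } else {
        SI <- processCol(blockI[, jj])
        outBlock[, jj] <- sqrt(Re(SR@values)^2 + Im(SR@values)^2 +
                                 Re(SI@values)^2 + Im(SI@values)^2)
      }
    }
    writeColBlock(out@planes[["r"]], j, outBlock)
    noteBufferCycle()
    j <- j + k
  }
  out
}
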