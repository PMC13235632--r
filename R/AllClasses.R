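#' @import methods
NULL

#' Acquisition parameters of a 2D FT-ICR experiment
#'
#' Describes the sampling geometry of a two-dimensional FT-ICR MS acquisition:
#' the magnetic field, the number and increment of the encoding delays (t1,
#' indirect/precursor dimension), the detection sampling (t2, direct/fragment
#' dimension), the detected frequency window and the frequency offset
#' subtracted from precursor cyclotron frequencies by the encoding pulse
#' sequence (the observed modulation frequency is the cyclotron frequency
#' minus \code{f1Offset}).
#'
#' @slot magneticField magnetic field, tesla.
#' @slot nT1 number of encoding increments (rows).
#' @slot dt1 t1 increment, seconds.
#' @slot nT2 samples per transient (columns).
#' @slot sampleRateT2 detection sampling rate, Hz.
#' @slot f2Low,f2High detected frequency window in the fragment dimension, Hz.
#' @slot f1Offset frequency subtracted from precursor cyclotron frequencies, Hz.
#'
#' @export
setClass("AcquisitionParams",
  representation(
    magneticField = "numeric",
    nT1 = "integer",
    dt1 = "numeric",
    nT2 = "integer",
    sampleRateT2 = "numeric",
    f2Low = "numeric",
    f2High = "numeric",
    f1Offset = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@nT1) != 1L || object@nT1 < 2L)
    msg <- c(msg, "nT1 must be a single integer >= 2")
  if (length(object@dt1) != 1L || !is.finite(object@dt1) || object@dt1 <= 0)
    msg <- c(msg, "dt1 must be > 0")
  if (length(object@nT2) != 1L || object@nT2 < 2L)
    msg <- c(msg, "nT2 must be >= 2")
  if (object@sampleRateT2 <= 0)
    msg <- c(msg, "sampleRateT2 must be > 0")
  if (object@magneticField <= 0)
    msg <- c(msg, "magneticField must be > 0")
  if (object@f2Low >= object@f2High)
    msg <- c(msg, "f2Low must be < f2High")
  if (object@f1Offset < 0)
    msg <- c(msg, "f1Offset must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' @param magneticField magnetic field in tesla.
#' @param nT1 number of t1 encoding increments.
#' @param dt1 t1 increment in seconds; the indirect bandwidth is
#'   \code{1/(2*dt1)}.
#' @param nT2 number of samples per transient.
#' @param sampleRateT2 detection sampling rate in Hz.
#' @param f2Low,f2High detected frequency window (fragment dimension), Hz.
#'   Defaults to the full Nyquist band.
#' @param f1Offset frequency subtracted from precursor cyclotron frequencies
#'   by the encoding, Hz.
#' @return an \code{AcquisitionParams} object.
#' @examples
#' acquisitionParams(15, nT1 = 64, dt1 = 2e-6, nT2 = 1024, sampleRateT2 = 1e6)
#' @export
acquisitionParams <- function(magneticField, nT1, dt1, nT2, sampleRateT2,
                              f2Low = 0, f2High = sampleRateT2 / 2,
                              f1Offset = 0) {
  new("AcquisitionParams",
      magneticField = as.numeric(magneticField),
      nT1 = as.integer(nT1), dt1 = as.numeric(dt1),
      nT2 = as.integer(nT2), sampleRateT2 = as.numeric(sampleRateT2),
      f2Low = as.numeric(f2Low), f2High = as.numeric(f2High),
      f1Offset = as.numeric(f1Offset))
}

#' Acquisition time of the direct dimension
#' @param params an \code{AcquisitionParams}.
#' @return seconds of detection per transient, \code{nT2/sampleRateT2}.
#' @export
acquisitionTimeT2 <- function(params) params@nT2 / params@sampleRateT2

#' Indirect (precursor) bandwidth
#' @param params an \code{AcquisitionParams}.
#' @return the indirect Nyquist bandwidth \code{1/(2*dt1)} in Hz.
#' @export
indirectBandwidth <- function(params) 1 / (2 * params@dt1)

#' Axis description for scans and grid dimensions
#'
#' @slot kind one of \code{"time"}, \code{"frequency"}, \code{"mz"}.
#' @slot nPoints number of points.
#' @slot start value of the first point (s, Hz or Th).
#' @slot step spacing between points (positive).
#' @slot descending whether increasing index means decreasing physical
#'   frequency/m-z (display orientation; values are stored ascending).
#' @export
setClass("AxisSpec",
  representation(kind = "character", nPoints = "integer",
                 start = "numeric", step = "numeric", descending = "logical")
)

setValidity("AxisSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("time", "frequency", "mz"))
    msg <- c(msg, "kind must be time, frequency or mz")
  if (object@nPoints < 1L) msg <- c(msg, "nPoints must be >= 1")
  if (!is.finite(object@step) || object@step <= 0)
    msg <- c(msg, "step must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct an axis
#' @param kind \code{"time"}, \code{"frequency"} or \code{"mz"}.
#' @param nPoints number of points.
#' @param start first axis value.
#' @param step point spacing (> 0).
#' @param descending orientation flag (see \code{\linkS4class{AxisSpec}}).
#' @return an \code{AxisSpec}.
#' @export
axisSpec <- function(kind, nPoints, start, step, descending = FALSE) {
  new("AxisSpec", kind = kind, nPoints = as.integer(nPoints),
      start = as.numeric(start), step = as.numeric(step),
      descending = descending)
}

#' Axis values
#' @param axis an \code{AxisSpec}.
#' @return numeric vector \code{start + (0:(nPoints-1)) * step}.
#' @export
axisValues <- function(axis) axis@start + (seq_len(axis@nPoints) - 1L) * axis@step

#' A one-dimensional scan
#'
#' A single row or column of a 2D data set, or a derived 1D spectrum:
#' a transient, a fragment ion scan (horizontal slice at one precursor m/z),
#' a precursor ion scan (vertical slice at one fragment m/z), or the
#' autocorrelation line.
#'
#' @slot values numeric or complex vector.
#' @slot axis the matching \code{AxisSpec}.
#' @slot origin free-form origin tag, e.g. \code{"fragment-ion-scan mz=576.32"}.
#' @export
setClass("Scan",
  representation(values = "ANY", axis = "AxisSpec", origin = "character"))

setValidity("Scan", function(object) {
  if (!(is.numeric(object@values) || is.complex(object@values)))
    return("values must be numeric or complex")
  if (length(object@values) != object@axis@nPoints)
    return(sprintf("length of values (%d) does not match axis nPoints (%d)",
                   length(object@values), object@axis@nPoints))
  TRUE
})

#' Construct a scan
#' @param values numeric or complex vector.
#' @param axis an \code{AxisSpec} of matching length.
#' @param origin origin tag.
#' @return a \code{Scan}.
#' @export
scan1d <- function(values, axis, origin = "unspecified") {
  new("Scan", values = values, axis = axis, origin = origin)
}

#' @describeIn scan1d values accessor
#' @param x a \code{Scan}.
#' @export
scanValues <- function(x) x@values

#' @describeIn scan1d axis accessor
#' @export
scanAxis <- function(x) x@axis

#' Phase-correction coefficients for both dimensions
#'
#' The phase correction is quadratic in the directly detected fragment (F2)
#' frequency and linear in the indirectly detected precursor (F1) frequency;
#' the two coefficient sets are independent. Correction multiplies a spectrum
#' point at frequency f by \code{exp(-1i * (a0 + a1*f + a2*f^2))} (F2) or
#' \code{exp(-1i * (b0 + b1*f))} (F1).
#'
#' @slot a0,a1,a2 F2 coefficients: rad, rad/Hz, rad/Hz^2.
#' @slot b0,b1 F1 coefficients: rad, rad/Hz.
#' @export
setClass("PhaseFunction2D",
  representation(a0 = "numeric", a1 = "numeric", a2 = "numeric",
                 b0 = "numeric", b1 = "numeric"))

setValidity("PhaseFunction2D", function(object) {
  v <- c(object@a0, object@a1, object@a2, object@b0, object@b1)
  if (length(v) != 5L || any(!is.finite(v))) "all five coefficients must be finite scalars" else TRUE
})

#' Construct a 2D phase function
#' @param a0,a1,a2 quadratic F2 (fragment) coefficients (rad, rad/Hz, rad/Hz^2).
#' @param b0,b1 linear F1 (precursor) coefficients (rad, rad/Hz).
#' @return a \code{PhaseFunction2D}.
#' @export
phaseFunction2d <- function(a0 = 0, a1 = 0, a2 = 0, b0 = 0, b1 = 0) {
  new("PhaseFunction2D", a0 = as.numeric(a0), a1 = as.numeric(a1),
      a2 = as.numeric(a2), b0 = as.numeric(b0), b1 = as.numeric(b1))
}

#' Quadratic frequency-to-m/z calibration
#'
#' m/z = c1/f + c2/f^2, the two-term calibration law standard for ICR:
#' c1 carries the ideal cyclotron term eB/(2 pi u), c2 absorbs field
#' imperfections and space-charge/magnetron shifts.
#'
#' @slot c1 Hz.Th coefficient of 1/f (> 0).
#' @slot c2 Hz^2.Th coefficient of 1/f^2.
#' @slot fRange frequency interval over which the fit is valid, Hz.
#' @export
setClass("CalibrationQuadratic",
  representation(c1 = "numeric", c2 = "numeric", fRange = "numeric"))

setValidity("CalibrationQuadratic", function(object) {
  msg <- character()
  if (!is.finite(object@c1) || object@c1 <= 0) msg <- c(msg, "c1 must be > 0")
  if (!is.finite(object@c2)) msg <- c(msg, "c2 must be finite")
  if (length(object@fRange) != 2L || object@fRange[1] <= 0 ||
      object@fRange[1] >= object@fRange[2])
    msg <- c(msg, "fRange must be an increasing positive interval")
  if (length(msg)) msg else TRUE
})

#' Autoregressive signal model (backward linear prediction)
#'
#' Models a real sampled signal as a finite sum of exponentially damped
#' sinusoids x(n) = sum_k alpha_k z_k^n with poles z_k = exp(gamma_k + i
#' omega_k). Used to recalculate corrupted initial points of precursor ion
#' scans by backward prediction.
#'
#' @slot order number of poles p.
#' @slot coefficients backward linear-prediction coefficients c_k such that
#'   x(n) = sum_{k=1..p} c_k x(n+k).
#' @slot poles complex poles z_k.
#' @slot amplitudes complex amplitudes alpha_k.
#' @export
setClass("ARModel",
  representation(order = "integer", coefficients = "numeric",
                 poles = "complex", amplitudes = "complex"))

setValidity("ARModel", function(object) {
  if (object@order < 1L) return("order must be >= 1")
  if (length(object@coefficients) != object@order)
    return("coefficients length must equal order")
  TRUE
})

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf("AcquisitionParams: B = %g T, %d x %d (t1 x t2)\n",
              object@magneticField, object@nT1, object@nT2))
  cat(sprintf("  dt1 = %g s (indirect bandwidth %.6g Hz), sample rate %g Hz\n",
              object@dt1, indirectBandwidth(object), object@sampleRateT2))
  cat(sprintf("  F2 window [%.6g, %.6g] Hz, f1 offset %.6g Hz\n",
              object@f2Low, object@f2High, object@f1Offset))
})

setMethod("show", "AxisSpec", function(object) {
  cat(sprintf("AxisSpec(%s): %d points, start %.8g, step %.8g%s\n",
              object@kind, object@nPoints, object@start, object@step,
              if (object@descending) " (display descending)" else ""))
})

setMethod("show", "Scan", function(object) {
  cat(sprintf("Scan [%s], %d %s points (%s)\n", object@origin,
              object@axis@nPoints, object@axis@kind,
              if (is.complex(object@values)) "complex" else "real"))
})

setMethod("show", "PhaseFunction2D", function(object) {
  cat(sprintf("PhaseFunction2D: F2 (a0=%.6g rad, a1=%.6g rad/Hz, a2=%.6g rad/Hz^2)\n",
              object@a0, object@a1, object@a2))
  cat(sprintf("                 F1 (b0=%.6g rad, b1=%.6g rad/Hz)\n",
              object@b0, object@b1))
})

setMethod("show", "CalibrationQuadratic", function(object) {
  cat(sprintf("CalibrationQuadratic: m/z = %.10g/f + %.10g/f^2, valid f in [%.6g, %.6g] Hz\n",
              object@c1, object@c2, object@fRange[1], object@fRange[2]))
})

setMethod("show", "ARModel", function(object) {
  cat(sprintf("ARModel: order %d, pole frequencies (rad/sample): %s\n",
              object@order,
              paste(sprintf("%.4f", Arg(object@poles)), collapse = ", ")))
})
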