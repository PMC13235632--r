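# Phase-coefficient estimation. Seeding: the phase of the complex spectrum
# at each peak bin is measured, unwrapped across peaks ordered by frequency,
# and fitted with the phase model (quadratic for F2, linear for F1).
# Refinement: Nelder-Mead on the absorption objective -- maximize the summed
# real-part peak height penalized by the integrated negative baseline in
# peak neighborhoods (penalty weight lambda = 1).

.unwrapPhases <- function(theta) {
  out <- theta
  for (k in seq_along(theta)[-1]) {
    d <- theta[k] - out[k - 1]
    out[k] <- out[k - 1] + atan2(sin(d), cos(d))
  }
  out
}

.wrapPhase <- function(x) atan2(sin(x), cos(x))

.phaseObjective <- function(values, f, peakBins, coef, halfWidth = 10L) {
  phi <- coef[1] + coef[2] * f + if (length(coef) > 2L) coef[3] * f^2 else 0
  re <- Re(values * exp(-1i * phi))
  height <- sum(re[peakBins])
  negArea <- 0
  n <- length(re)
  for (p in peakBins) {
    lo <- max(1L, p - halfWidth); hi <- min(n, p + halfWidth)
    seg <- re[lo:hi]
    negArea <- negArea + sum(abs(seg[seg < 0]))
  }
  height - negArea   # lambda = 1
}

.fitPhasePoly <- function(spectrum, peakBins, degree) {
  f <- axisValues(spectrum@axis)[peakBins]
  theta <- Arg(spectrum@values[peakBins])
  ord <- order(f)
  thetaU <- .unwrapPhases(theta[ord])
  X <- stats::poly(f[ord], degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), thetaU)
  coef <- fit$coefficients
  coef[is.na(coef)] <- 0
  unname(coef)
}

#' Estimate phase-correction coefficients from peaks
#'
#' \code{optimizePhaseF2} recovers the quadratic fragment-dimension
#' coefficients (a0, a1, a2) from a 1D complex spectrum with at least three
#' resolved peaks; \code{optimizePhaseF1} recovers the linear precursor
#' coefficients (b0, b1) from one precursor ion scan (or the coherent sum of
#' several, supplied as a list) with at least two peaks. The measured peak
#' phases seed a polynomial fit, refined by Nelder-Mead on a real-part
#' height objective penalized by negative-lobe area around the peaks.
#'
#' @param spectrum a complex frequency-domain \code{\linkS4class{Scan}}.
#' @param peakBins 1-based bin indices of resolved peaks.
#' @param refine run the Nelder-Mead refinement (default TRUE).
#' @return named numeric coefficients: \code{c(a0, a1, a2)} or
#'   \code{c(b0, b1)}; \code{a0}/\code{b0} wrapped into (-pi, pi].
#' @export
optimizePhaseF2 <- function(spectrum, peakBins, refine = TRUE) {
  if (length(peakBins) < 3L)
    stop("optimization error: at least 3 peaks are required for the quadratic F2 fit")
  coef <- .fitPhasePoly(spectrum, peakBins, degree = 2L)
  coef <- .refinePhase(spectrum, peakBins, coef, refine)
  stats::setNames(c(.wrapPhase(coef[1]), coef[2], coef[3]),
                  c("a0", "a1", "a2"))
}

#' @rdname optimizePhaseF2
#' @param scans a \code{Scan} or list of \code{Scan}s to sum before the F1
#'   fit (summing multiple precursor ion scans prior to phase correction
#'   improves the estimate when individual scans have few peaks).
#' @export
optimizePhaseF1 <- function(scans, peakBins, refine = TRUE) {
  if (is(scans, "Scan")) scans <- list(scans)
  if (length(peakBins) < 2L)
    stop("optimization error: at least 2 peaks are required for the linear F1 fit")
  vals <- Reduce(`+`, lapply(scans, scanValues))
  spectrum <- scan1d(vals, scans[[1]]@axis, "summed precursor scans")
  coef <- .fitPhasePoly(spectrum, peakBins, degree = 1L)
  coef <- .refinePhase(spectrum, peakBins, coef, refine)
  stats::setNames(c(.wrapPhase(coef[1]), coef[2]), c("b0", "b1"))
}

.refinePhase <- function(spectrum, peakBins, coef, refine) {
  if (!refine) return(coef)
  f <- axisValues(spectrum@axis)
  scale <- pmax(abs(coef), c(0.1, 1e-6, 1e-12)[seq_along(coef)])
  res <- stats::optim(coef,
                      function(p) -.phaseObjective(spectrum@values, f,
                                                   peakBins, p),
                      method = "Nelder-Mead",
                      control = list(maxit = 500,
                                     parscale = scale,
                                     reltol = 1e-12))
  res$par
}
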