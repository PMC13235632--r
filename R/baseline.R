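# Autoregressive backward-prediction baseline correction. The t1-domain
# signal of each precursor ion scan is a finite sum of exponentially damped
# sinusoids x(n) = sum_k alpha_k z_k^n, z_k = exp(gamma_k + i omega_k), so a
# clean trailing segment determines the initial points: backward linear
# prediction x(n) = sum_{k=1..p} c_k x(n+k) is fitted by least squares on
# the trailing segment, the poles are the roots of the backward-prediction
# polynomial, the amplitudes follow by a linear fit, and the corrupted
# initial points are recomputed from the parametric model.

#' Fit a backward linear-prediction model
#'
#' Least-squares fit of the backward prediction x(n) = sum_{k=1..p} c_k
#' x(n+k) on the trailing segment of the scan, solved with singular-value
#' truncation (singular values below max(sigma) * 1e-10 are dropped; the
#' exact-pole model is otherwise ill-conditioned in the presence of noise).
#' Poles are the roots z of sum_k c_k z^k = 1 and amplitudes are fitted to
#' the same segment.
#'
#' @param scan a real \code{\linkS4class{Scan}} (time/indirect-domain
#'   values) or numeric vector of length N > 2p.
#' @param order model order p (number of poles; 2 per real damped cosine).
#' @param skip number of leading points excluded from the fit (e.g. the
#'   corrupted points later replaced).
#' @return an \code{\linkS4class{ARModel}}.
#' @examples
#' n <- 0:199
#' x <- exp(-n / 150) * cos(2 * pi * 0.11 * n + 0.3)
#' m <- fitARBackward(x, order = 2)
#' sort(abs(Arg(m@poles))) / (2 * pi)  # ~0.11
#' @export
fitARBackward <- function(scan, order, skip = 0L) {
  x <- if (is(scan, "Scan")) scan@values else scan
  if (is.complex(x)) stop("fit error: expected a real-valued scan")
  p <- as.integer(order)
  if (p < 1L) stop("fit error: order must be >= 1")
  N <- length(x)
  if (N <= 2L * p)
    stop(sprintf("fit error: scan length %d must exceed 2 * order = %d",
                 N, 2L * p))
  skip <- as.integer(skip)
  if (all(x == 0))
    return(new("ARModel", order = p, coefficients = numeric(p),
               poles = complex(p), amplitudes = complex(p)))
  # rows: x[n] ~ sum_k c_k x[n+k], n over the clean segment
  n0 <- max(1L, skip + 1L)
  rows <- n0:(N - p)
  if (length(rows) < p)
    stop("fit error: too few clean points for the requested order")
  A <- vapply(seq_len(p), function(k) x[rows + k], numeric(length(rows)))
  b <- x[rows]
  sv <- svd(A)
  keep <- sv$d > max(sv$d) * 1e-10
  if (!any(keep)) keep[1] <- TRUE
  if (sum(keep) < p)
    warning("rank-deficient backward-prediction system; solution regularized by SVD truncation")
  cvec <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep])
  cvec <- as.numeric(cvec)
  # poles: roots of  c_p z^p + ... + c_1 z - 1 = 0
  poles <- polyroot(c(-1, cvec))
  # amplitudes: least-squares fit of x(n) = sum_k alpha_k z_k^n on the segment
  nIdx <- n0:N
  V <- vapply(poles, function(z) z^nIdx, complex(length(nIdx)))
  sva <- svd(V)
  keepA <- sva$d > max(sva$d) * 1e-10
  alpha <- sva$v[, keepA, drop = FALSE] %*%
    ((Conj(t(sva$u[, keepA, drop = FALSE])) %*% x[nIdx]) / sva$d[keepA])
  new("ARModel", order = p, coefficients = cvec,
      poles = as.complex(poles), amplitudes = as.complex(alpha))
}

#' Evaluate an AR model at sample indices
#' @param model an \code{\linkS4class{ARModel}}.
#' @param n 1-based sample indices.
#' @return real part of sum_k alpha_k z_k^n.
#' @export
predictAR <- function(model, n) {
  if (model@order < 1L || !length(model@poles)) return(numeric(length(n)))
  V <- vapply(seq_along(model@poles),
              function(k) model@poles[k]^n, complex(length(n)))
  Re(as.vector(V %*% model@amplitudes))
}

#' Replace corrupted initial points by backward extrapolation
#'
#' The first \code{nReplace} points of the scan are replaced by the
#' parametric AR model's prediction; all other points are untouched. Exact
#' on noiseless p-pole signals.
#'
#' @param scan a real \code{\linkS4class{Scan}} or numeric vector.
#' @param model an \code{\linkS4class{ARModel}} fitted on the clean trailing
#'   segment.
#' @param nReplace number of initial points to recalculate (P). Must satisfy
#'   P < N - p.
#' @return the corrected scan (same type as the input).
#' @export
replaceInitialPoints <- function(scan, model, nReplace) {
  isScan <- is(scan, "Scan")
  x <- if (isScan) scan@values else scan
  P <- as.integer(nReplace)
  if (P == 0L) return(scan)
  N <- length(x)
  if (P < 0L || P >= N - model@order)
    stop(sprintf("range error: nReplace = %d must satisfy 0 <= P < N - p = %d",
                 P, N - model@order))
  x[seq_len(P)] <- predictAR(model, seq_len(P))
  if (isScan) scan1d(x, scan@axis, scan@origin) else x
}

#' Estimate the AR order from the scan's spectrum
#'
#' The number of poles needed is about twice the number of resolved peaks in
#' the scan's spectrum (each real damped cosine contributes a conjugate pole
#' pair). Peaks are counted as local maxima of the magnitude spectrum above
#' 3 x noise (noise = mean magnitude of the lowest decile); the result is
#' clipped to [2, N/4].
#'
#' @param scan real \code{\linkS4class{Scan}} or numeric vector.
#' @return integer order.
#' @export
autoAROrder <- function(scan) {
  x <- if (is(scan, "Scan")) scan@values else scan
  N <- length(x)
  mag <- Mod(stats::fft(x))[seq_len(max(2L, N %/% 2L))]
  noise <- mean(sort(mag)[seq_len(max(1L, length(mag) %/% 10L))])
  if (noise == 0) noise <- .Machine$double.eps
  isMax <- mag > c(-Inf, mag[-length(mag)]) & mag >= c(mag[-1], -Inf)
  npk <- sum(isMax & mag > 3 * noise)
  as.integer(min(max(2L, 2L * npk), max(2L, N %/% 4L)))
}

#' Baseline-correct a precursor ion scan
#'
#' Convenience composition: fit the backward-prediction model on the scan's
#' clean trailing segment (excluding the first \code{nReplace} points, whose
#' rapidly accumulating phase makes them unreliable) and recalculate those
#' points from the model. Applying the correction twice is idempotent to
#' numerical tolerance on noiseless signals.
#'
#' @param scan real t1-domain \code{\linkS4class{Scan}} or numeric vector.
#' @param order AR order: integer, or \code{"auto"} (see
#'   \code{\link{autoAROrder}}).
#' @param nReplace number of initial points to recalculate (anchored, for
#'   real data sets, to the number of phase rotations of the fastest
#'   precursor signal; data-set-specific).
#' @return the corrected scan.
#' @export
correctScanBaseline <- function(scan, order = "auto", nReplace) {
  if (identical(order, "auto")) order <- autoAROrder(scan)
  x <- if (is(scan, "Scan")) scan@values else scan
  if (all(x == 0) || nReplace == 0L) return(scan)
  model <- fitARBackward(scan, order = order, skip = nReplace)
  replaceInitialPoints(scan, model, nReplace)
}
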