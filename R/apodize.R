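# Apodization windows. The workhorse is the asymmetric rise-and-fall window
# of Kilgour and Van Orden, which zeroes the corrupted start of the transient
# (baseline correction for absorption mode) while keeping most of the signal:
# a half-cosine rise reaching 1 at a fraction F of the transient, then a
# half-cosine fall back to 0. The "sqrt fall" variant takes the square root
# of the falling branch, losing less signal at the transient end when the
# acquisition cuts the decay short.

#' Apodization window specification
#'
#' @slot kind \code{"kv_asymmetric"}, \code{"kv_asymmetric_sqrt_fall"},
#'   \code{"sine_bell"} or \code{"none"}.
#' @slot F fraction of the transient length at which the window is maximal
#'   (in (0,1); 0.25 is the optimum reported for ICR transients).
#' @slot sineShift shift parameter of the sine bell, in [0,1).
#' @export
setClass("ApodizationSpec",
  representation(kind = "character", F = "numeric", sineShift = "numeric"))

.APOD_KINDS <- c("kv_asymmetric", "kv_asymmetric_sqrt_fall", "sine_bell", "none")

setValidity("ApodizationSpec", function(object) {
  msg <- character()
  if (!object@kind %in% .APOD_KINDS)
    msg <- c(msg, paste("unknown apodization kind:", object@kind))
  if (object@kind %in% c("kv_asymmetric", "kv_asymmetric_sqrt_fall") &&
      (object@F <= 0 || object@F >= 1))
    msg <- c(msg, "F must be in (0,1)")
  if (object@sineShift < 0 || object@sineShift >= 1)
    msg <- c(msg, "sineShift must be in [0,1)")
  if (length(msg)) msg else TRUE
})

#' Construct an apodization specification
#' @param kind window kind (see \code{\linkS4class{ApodizationSpec}}).
#' @param F fraction of the transient at the maximum (asymmetric kinds).
#' @param sineShift sine-bell shift in [0,1).
#' @return an \code{ApodizationSpec}.
#' @export
apodizationSpec <- function(kind = c("kv_asymmetric_sqrt_fall", "kv_asymmetric",
                                     "sine_bell", "none"),
                            F = 0.25, sineShift = 0) {
  kind <- match.arg(kind)
  new("ApodizationSpec", kind = kind, F = as.numeric(F),
      sineShift = as.numeric(sineShift))
}

#' Evaluate an apodization window
#'
#' Returns the weight vector of length \code{n}. For the asymmetric kinds the
#' rising branch over points 0..NF-1 is A(n) = (1 - cos(n pi / (NF-1))) / 2
#' and the falling branch is a half-cosine mapping [NF, N-1] onto the
#' argument interval [pi, 2 pi], i.e. A(n) = (1 + cos((n-NF) pi / (N-1-NF)))/2.
#' (The falling branch is sometimes printed as
#' A(n) = (1 - cos((n + N(1-F) - 1) pi / (N(1-F) - 1)))/2, which is not
#' continuous with the rising branch at n = NF for general N and F; the
#' half-cosine form implements the intended rise-to-F-then-fall profile.)
#' The sqrt-fall variant takes the square root of the falling branch only.
#' NF is rounded to the nearest integer for branch assignment; ties round
#' down.
#'
#' @param spec an \code{\linkS4class{ApodizationSpec}}.
#' @param n number of points (>= 4).
#' @return numeric weight vector in [0,1] of length \code{n}.
#' @examples
#' w <- apodWindow(apodizationSpec("kv_asymmetric", F = 0.25), 1000)
#' which.max(w)  # near 0.25 * 1000
#' @export
apodWindow <- function(spec, n) {
  n <- as.integer(n)
  if (n < 4L) stop("validation error: window length must be >= 4")
  if (spec@kind == "none") return(rep(1, n))
  if (spec@kind == "sine_bell") {
    idx <- seq_len(n) - 1L
    s <- spec@sineShift
    return(pmin(1, pmax(0, sin(pi * s + pi * (1 - s) * idx / (n - 1)))))
  }
  nf <- ceiling(n * spec@F - 0.5)  # nearest integer, ties down
  if (nf < 2L) stop("validation error: NF < 2; increase F or n")
  if (nf > n - 2L) stop("validation error: NF too close to n; decrease F")
  idx <- seq_len(n) - 1L
  w <- numeric(n)
  rise <- idx < nf
  w[rise] <- 0.5 * (1 - cos(idx[rise] * pi / (nf - 1)))
  fall <- !rise
  wf <- 0.5 * (1 + cos((idx[fall] - nf) * pi / (n - 1 - nf)))
  if (spec@kind == "kv_asymmetric_sqrt_fall") wf <- sqrt(wf)
  w[fall] <- wf
  w
}

#' Apply apodization to a scan
#'
#' Pointwise product of the scan values with the window; linear in the input.
#' \code{kind = "none"} is the identity.
#'
#' @param scan a \code{\linkS4class{Scan}} (time-domain values).
#' @param spec an \code{\linkS4class{ApodizationSpec}}.
#' @return the apodized \code{Scan}.
#' @export
applyApodization <- function(scan, spec) {
  if (spec@kind == "none") return(scan)
  w <- apodWindow(spec, length(scan@values))
  scan1d(scan@values * w, scan@axis, scan@origin)
}
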