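# Shared fixtures: small acquisition geometries and simulated data sets
# built in code, plus centroid helpers used by several test files.

simpleAcq <- function(n1 = 32L, n2 = 512L, sr = 1e6, dt1 = 2e-6, B = 15,
                      off = 0) {
  acquisitionParams(B, n1, dt1, n2, sr, f1Offset = off)
}

# precursor/fragment m/z chosen so that their frequencies land exactly on
# FT bins of the given geometry (no interpolation ambiguity in oracles)
onBinMz <- function(bin, step, B = 15) mzFromFrequency(bin * step, B)

f2Step <- function(acq) acq@sampleRateT2 / acq@nT2
f1Step <- function(acq) 1 / (acq@dt1 * acq@nT1)

# one precursor (F1 bin b1) with fragments at F2 bins b2
onBinSim <- function(acq, b1, b2, efficiency = NULL, tau = 2e-3,
                     phase = phaseFunction2d(), noiseSigma = 0, seed = 1L,
                     B = acq@magneticField) {
  if (is.null(efficiency)) efficiency <- 1 / length(b2)
  frs <- lapply(b2, function(b)
    c(mz = onBinMz(b, f2Step(acq), B), charge = 1, efficiency = efficiency))
  pr <- precursorSpec(mzFromFrequency(b1 * f1Step(acq) + acq@f1Offset, B),
                      fragments = frs)
  simConfig(acq, list(pr), tau = tau, phase = phase,
            noiseSigma = noiseSigma, seed = seed)
}

# apex of v restricted to a window around an expected index
apexNear <- function(v, center, halfWidth = 20L) {
  w <- max(2L, center - halfWidth):min(length(v) - 1L, center + halfWidth)
  w[which.max(v[w])]
}

# 3-point parabolic frequency centroid (independent of the package's picker)
parabFreq <- function(v, i, axis) {
  d <- 0.5 * (v[i - 1L] - v[i + 1L]) / (v[i - 1L] - 2 * v[i] + v[i + 1L])
  axisValues(axis)[i] + d * axis@step
}

# count local maxima above a threshold
countPeaksAbove <- function(v, thr) {
  n <- length(v)
  if (n < 3L) return(0L)
  inner <- 2:(n - 1L)
  sum(v[inner] > thr & v[inner] > v[inner - 1L] & v[inner] >= v[inner + 1L])
}
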