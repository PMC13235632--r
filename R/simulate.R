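# Synthetic 2D transient simulator. Emulates the encoding pulse sequence:
# precursor ion radii (and hence fragmentation efficiencies) are modulated
# along the encoding delay t1 at the precursor's modulation frequency
# (cyclotron frequency minus the encoding offset), so each fragment's signal
# amplitude is cosine-modulated along t1 while its own detected signal is an
# exponentially damped sinusoid along t2 with frequency-dependent phase:
#
#   s(t1, t2) = E * (1 + cos(2 pi nu1 t1 + b0 + b1 nu1)) / 2
#                 * cos(2 pi nu2 t2 + a0 + a1 nu2 + a2 nu2^2) * exp(-t2/tau)
#
# A linear efficiency-vs-radius law gives the (1+cos)/2 amplitude factor,
# which produces signal at the fundamental modulation frequency. Unfragmented
# precursor intensity (efficiency 1 - sum of fragment efficiencies, floored
# at 0) is emitted as a self-fragment, populating the autocorrelation line.
# The t1 signal is purely real: amplitude modulation, no phase cycling.

#' Precursor specification for the simulator
#'
#' @param mz precursor m/z, Th (> 0).
#' @param charge positive integer charge.
#' @param abundance relative abundance (> 0).
#' @param fragments list of fragments, each a named numeric vector
#'   \code{c(mz = , charge = , efficiency = )} with efficiency in (0, 1].
#' @param isotopes optional isotope pattern: list of \code{c(dmz = ,
#'   intensity = )} offsets applied to the precursor (and its modulation
#'   frequency), each with its own relative intensity.
#' @return a \code{PrecursorSpec} list.
#' @export
precursorSpec <- function(mz, charge = 1L, abundance = 1,
                          fragments = list(), isotopes = NULL) {
  if (mz <= 0) stop("validation error: precursor mz must be > 0")
  if (charge < 1L) stop("validation error: charge must be a positive integer")
  for (fr in fragments) {
    if (is.na(fr["efficiency"]) || fr[["efficiency"]] <= 0 ||
        fr[["efficiency"]] > 1)
      stop("validation error: fragment efficiency must be in (0, 1]")
    if (fr[["mz"]] <= 0) stop("validation error: fragment mz must be > 0")
  }
  structure(list(mz = mz, charge = as.integer(charge), abundance = abundance,
                 fragments = fragments, isotopes = isotopes),
            class = "PrecursorSpec")
}

#' Simulation configuration
#'
#' @param acquisition an \code{\linkS4class{AcquisitionParams}}.
#' @param precursors list of \code{\link{precursorSpec}}s.
#' @param tau damping time constant of the detected transients, seconds.
#' @param phase true phase coefficients used in the synthesis, a
#'   \code{\linkS4class{PhaseFunction2D}}.
#' @param noiseSigma white Gaussian noise standard deviation.
#' @param scintFraction scintillation-noise fraction: each point is further
#'   perturbed by Gaussian noise of sd \code{scintFraction * |signal|}
#'   (noise proportional to signal intensity).
#' @param seed RNG seed; a fixed seed makes the output bit-reproducible.
#' @return a \code{SimConfig} list.
#' @export
simConfig <- function(acquisition, precursors, tau = 0.1,
                      phase = phaseFunction2d(), noiseSigma = 0,
                      scintFraction = 0, seed = 1L) {
  if (tau <= 0) stop("validation error: tau must be > 0")
  if (noiseSigma < 0 || scintFraction < 0)
    stop("validation error: noise parameters must be >= 0")
  structure(list(acquisition = acquisition, precursors = precursors,
                 tau = tau, phase = phase, noiseSigma = noiseSigma,
                 scintFraction = scintFraction, seed = as.integer(seed)),
            class = "SimConfig")
}

.simLines <- function(cfg) {
  acq <- cfg$acquisition
  B <- acq@magneticField
  rows <- list()
  for (pr in cfg$precursors) {
    effSum <- sum(vapply(pr$fragments, function(fr) fr[["efficiency"]], 0))
    frags <- pr$fragments
    self <- max(0, 1 - effSum)
    if (self > 0)
      frags <- c(frags, list(c(mz = pr$mz, charge = pr$charge,
                               efficiency = self)))
    isos <- if (is.null(pr$isotopes)) list(c(dmz = 0, intensity = 1))
            else pr$isotopes
    for (iso in isos) {
      pmz <- pr$mz + iso[["dmz"]]
      nu1 <- cyclotronFrequency(pmz, B) - acq@f1Offset
      if (nu1 <= 0 || nu1 > indirectBandwidth(acq))
        stop(sprintf("configuration error: modulation frequency %.1f Hz for precursor m/z %.4f outside the indirect bandwidth [0, %.1f] Hz",
                     nu1, pmz, indirectBandwidth(acq)))
      for (fr in frags) {
        fmz <- fr[["mz"]] + if (fr[["mz"]] == pr$mz) iso[["dmz"]] else 0
        nu2 <- cyclotronFrequency(fmz, B)
        if (nu2 < acq@f2Low || nu2 > acq@f2High)
          stop(sprintf("configuration error: detected frequency %.1f Hz for fragment m/z %.4f outside the F2 window [%.1f, %.1f] Hz",
                       nu2, fmz, acq@f2Low, acq@f2High))
        amp <- pr$abundance * iso[["intensity"]] * fr[["efficiency"]]
        rows[[length(rows) + 1L]] <-
          data.frame(precursor_mz = pmz, fragment_mz = fmz, amplitude = amp,
                     nu1_hz = nu1, nu2_hz = nu2)
      }
    }
  }
  if (!length(rows))
    return(data.frame(precursor_mz = numeric(0), fragment_mz = numeric(0),
                      amplitude = numeric(0), nu1_hz = numeric(0),
                      nu2_hz = numeric(0)))
  do.call(rbind, rows)
}

#' Generate a synthetic 2D transient data set
#'
#' Synthesizes the raw N1 x N2 real grid row by row from the signal model
#' above and returns it with the ground-truth line table.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param backing \code{"memory"} or \code{"file"} for the grid.
#' @param dir scratch directory for file backing.
#' @return list with \code{dataset} (a raw-stage
#'   \code{\linkS4class{Dataset2D}}) and \code{truth} (data frame:
#'   precursor_mz, fragment_mz, amplitude, nu1_hz, nu2_hz).
#' @examples
#' cfg <- simConfig(acquisitionParams(15, 16, 2e-6, 128, 1e6),
#'                  precursors = list(precursorSpec(900)))
#' sim <- generateDataset2d(cfg)
#' sim$truth
#' @export
generateDataset2d <- function(cfg, backing = c("memory", "file"),
                              dir = tempdir()) {
  backing <- match.arg(backing)
  acq <- cfg$acquisition
  truth <- .simLines(cfg)
  n1 <- acq@nT1; n2 <- acq@nT2
  axis1 <- axisSpec("time", n1, 0, acq@dt1)
  axis2 <- axisSpec("time", n2, 0, 1 / acq@sampleRateT2)
  d <- emptyDataset2d(n1, n2, axis1, axis2, "raw", acq,
                      planes = "r", backing = backing, dir = dir,
                      provenance = list(simulated = TRUE, seed = cfg$seed,
                                        tau = cfg$tau))
  t2 <- axisValues(axis2)
  ph <- cfg$phase
  if (nrow(truth)) {
    # Precompute each line's t2 waveform once; per row only the t1 amplitude
    # factor changes.
    wave2 <- lapply(seq_len(nrow(truth)), function(k) {
      nu2 <- truth$nu2_hz[k]
      cos(2 * pi * nu2 * t2 + ph@a0 + ph@a1 * nu2 + ph@a2 * nu2^2) *
        exp(-t2 / cfg$tau)
    })
  }
  set.seed(cfg$seed)
  for (i in seq_len(n1)) {
    row <- numeric(n2)
    if (nrow(truth)) {
      t1 <- (i - 1L) * acq@dt1
      for (k in seq_len(nrow(truth))) {
        nu1 <- truth$nu1_hz[k]
        a1 <- truth$amplitude[k] *
          (1 + cos(2 * pi * nu1 * t1 + ph@b0 + ph@b1 * nu1)) / 2
        row <- row + a1 * wave2[[k]]
      }
    }
    if (cfg$scintFraction > 0) {    # proportional to the clean signal
      nz <- row != 0
      row[nz] <- row[nz] +
        stats::rnorm(sum(nz)) * cfg$scintFraction * abs(row[nz])
    }
    if (cfg$noiseSigma > 0)
      row <- row + stats::rnorm(n2, sd = cfg$noiseSigma)
    putRow(d, i, row)
    noteBufferCycle()
  }
  list(dataset = d, truth = truth)
}

#' Add noise to an existing data set
#'
#' White Gaussian noise of sd \code{sigma} everywhere, plus scintillation
#' noise: each point perturbed by Gaussian noise of sd
#' \code{scintFraction * |value|} (exactly zero values stay zero).
#'
#' @param d a \code{\linkS4class{Dataset2D}} (modified row by row).
#' @param sigma white-noise standard deviation (>= 0).
#' @param scintFraction proportional-noise fraction (>= 0).
#' @param seed RNG seed.
#' @return the data set, invisibly (storage modified in place).
#' @export
addNoise <- function(d, sigma, scintFraction = 0, seed = 1L) {
  if (sigma < 0 || scintFraction < 0)
    stop("validation error: sigma and scintFraction must be >= 0")
  if (sigma == 0 && scintFraction == 0) return(invisible(d))
  set.seed(as.integer(seed))
  n <- gridDims(d)
  for (i in seq_len(n[1])) {
    row <- scanValues(getRow(d, i))
    if (scintFraction > 0) {    # proportional to the stored signal
      nz <- row != 0
      row[nz] <- row[nz] + stats::rnorm(sum(nz)) * scintFraction * abs(row[nz])
    }
    if (sigma > 0) row <- row + stats::rnorm(n[2], sd = sigma)
    putRow(d, i, row)
    noteBufferCycle()
  }
  invisible(d)
}
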