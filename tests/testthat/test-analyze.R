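test_that("noise level is the mean absolute intensity; SNR divides by it", {
  ax <- axisSpec("frequency", 128L, 0, 100)
  v <- numeric(128); v[1:20] <- c(3, -3)[1 + (0:19) %% 2]   # |v| = 3
  v[64] <- 30
  s <- scan1d(v, ax)
  est <- noiseLevel(s, c(1L, 20L))
  expect_equal(est@level, 3)
  expect_equal(snr(s, 64L, est), 10)
  expect_identical(snr(s, 64L, 0), Inf)
  expect_error(noiseLevel(s, c(1L, 4L)), "validation error")
  expect_error(noiseLevel(s, c(100L, 200L)), "validation error")
})

test_that("Gaussian noise level estimates the folded-normal mean", {
  set.seed(31)
  v <- rnorm(1e5, sd = 2)
  est <- noiseLevel(scan1d(v, axisSpec("frequency", 1e5, 0, 1)), c(1L, 1e5L))
  expect_equal(est@level, 2 * sqrt(2 / pi), tolerance = 0.02)
})

test_that("resolving power matches a closed-form Lorentzian and scales with f0", {
  f <- seq(0, 5e5, by = 100)
  gammaHalf <- 500   # HWHM in Hz -> FWHM 1000
  mk <- function(f0) scan1d(gammaHalf^2 / ((f - f0)^2 + gammaHalf^2),
                            axisSpec("frequency", length(f), 0, 100))
  r1 <- resolvingPower(mk(2e5), which.min(abs(f - 2e5)))
  expect_equal(r1, 2e5 / 1000, tolerance = 0.02)
  r2 <- resolvingPower(mk(4e5), which.min(abs(f - 4e5)))
  expect_equal(r2 / r1, 2, tolerance = 0.02)
  # indirect-dimension offset restores the absolute frequency
  r3 <- resolvingPower(mk(2e5), which.min(abs(f - 2e5)), fOffset = 2e5)
  expect_equal(r3 / r1, 2, tolerance = 1e-6)
})

test_that("scan extraction returns the nearest row/column with the right axis", {
  acq <- simpleAcq(n1 = 32L, n2 = 256L, off = 1e5)
  cal <- theoreticalCalibration(15)
  cfg <- onBinSim(acq, b1 = 9L, b2 = 60L, efficiency = 1, tau = 5e-4)
  sim <- generateDataset2d(cfg)
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("none"),
                    apodF1 = apodizationSpec("none"), backing = "memory")
  tr <- sim$truth[1, ]
  fs <- extractFragmentScan(a, tr$precursor_mz, cal)
  expect_length(scanValues(fs), gridDims(a)[2])
  expect_identical(which.max(scanValues(fs)), 61L)
  ps <- extractPrecursorScan(a, tr$fragment_mz, cal)
  expect_length(scanValues(ps), gridDims(a)[1])
  expect_identical(apexNear(scanValues(ps), 10L, 4L), 10L)
  expect_error(extractFragmentScan(a, 1e6, cal), "range error")
  expect_error(extractPrecursorScan(a, 1e-3, cal), "range error")
  # m/z display descends as frequency ascends
  mzv <- scanMzValues(fs, cal)
  expect_true(all(diff(mzv[-1]) < 0))
})

test_that("a self-fragmenting precursor peaks on the autocorrelation line", {
  acq <- simpleAcq(n1 = 32L, n2 = 256L, off = 2e5)
  cal <- theoreticalCalibration(15)
  pm <- onBinMz(80L, f2Step(acq))
  pr <- precursorSpec(pm, fragments = list(
    c(mz = onBinMz(30L, f2Step(acq)), charge = 1, efficiency = 0.4)))
  sim <- generateDataset2d(simConfig(acq, list(pr), tau = 5e-4))
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("none"),
                    apodF1 = apodizationSpec("none"), backing = "memory")
  ac <- autocorrelationLine(a, cal)
  expect_identical(which.max(scanValues(ac)), 81L)
  expect_identical(ac@origin, "autocorrelation")
})

test_that("a shared fragment shows both precursors in its precursor ion scan", {
  acq <- simpleAcq(n1 = 64L, n2 = 256L)
  cal <- theoreticalCalibration(15)
  sharedMz <- onBinMz(70L, f2Step(acq))
  mk <- function(b1) precursorSpec(onBinMz(b1, f1Step(acq)), fragments = list(
    c(mz = sharedMz, charge = 1, efficiency = 1)))
  sim <- generateDataset2d(simConfig(acq, list(mk(11L), mk(21L)), tau = 5e-4))
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("none"),
                    apodF1 = apodizationSpec("none"), backing = "memory")
  ps <- scanValues(extractPrecursorScan(a, sharedMz, cal))
  # empty segments away from the zero-frequency ridge and both peaks
  noise <- mean(abs(ps[setdiff(5:32, c(11:13, 21:23))]))
  expect_identical(countPeaksAbove(ps[2:32], 3 * noise), 2L)
})

test_that("summing scans is linear and raises the SNR of weak isotopologues", {
  acq <- simpleAcq(n1 = 64L, n2 = 512L)
  cal <- theoreticalCalibration(15)
  f1s <- f1Step(acq)
  # precursor with a 5-peak isotope envelope, one shared fragment, noise
  pm <- onBinMz(20L, f1s)
  relInt <- c(1, 0.8, 0.5, 0.25, 0.1)
  iso <- lapply(0:4, function(k)
    c(dmz = onBinMz(20L + k, f1s) - pm, intensity = relInt[k + 1]))
  pr <- precursorSpec(pm, fragments = list(
    c(mz = onBinMz(120L, f2Step(acq)), charge = 1, efficiency = 1)),
    isotopes = iso)
  sim <- generateDataset2d(simConfig(acq, list(pr), tau = 5e-4,
                                     noiseSigma = 0.4, seed = 17L))
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("none"),
                    apodF1 = apodizationSpec("none"), backing = "memory")
  s1 <- getRow(a, 25L)                     # weakest isotopologue row alone
  expect_equal(scanValues(sumScans(a, rows = 25L)), scanValues(s1))
  expect_equal(scanValues(sumScans(a, rows = c(25L, 25L))),
               2 * scanValues(s1))
  summed <- sumScans(a, rows = 21:25)      # cover the envelope
  reg <- c(180L, 230L)
  snrSingle <- snr(s1, 121L, noiseLevel(s1, reg))
  snrSummed <- snr(summed, 121L, noiseLevel(summed, reg))
  expect_gt(snrSummed, snrSingle)
  expect_error(sumScans(a), "validation error")
  expect_error(sumScans(a, rows = integer(0)), "validation error")
})

test_that("2D peak picking finds nothing in zero data and centroids single lines", {
  acq <- simpleAcq(n1 = 32L, n2 = 256L)
  zero <- generateDataset2d(simConfig(acq, list(), tau = 1e-3))$dataset
  az <- absorption2d(zero, phaseFunction2d(), backing = "memory")
  expect_identical(nrow(pickPeaks2d(az, 3, noise = 1)), 0L)

  cal <- theoreticalCalibration(15)
  cfg <- onBinSim(acq, b1 = 9L, b2 = 60L, efficiency = 1, tau = 5e-4)
  sim <- generateDataset2d(cfg)
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("none"),
                    apodF1 = apodizationSpec("none"), backing = "memory")
  pk <- pickPeaks2d(a, 3, noise = 1, calF1 = cal)
  main <- pk[which.max(pk$intensity), ]
  tr <- sim$truth[1, ]
  expect_lt(abs(main$f1_hz - tr$nu1_hz), 0.2 * rowAxis(a)@step)
  expect_lt(abs(main$f2_hz - tr$nu2_hz), 0.2 * colAxis(a)@step)
  expect_equal(main$precursor_mz, tr$precursor_mz, tolerance = 1e-6)
  expect_equal(main$fragment_mz, tr$fragment_mz, tolerance = 1e-6)
  expect_gt(main$snr_f1, 3); expect_gt(main$snr_f2, 3)

  # invariance under uniform intensity scaling
  for (i in seq_len(gridDims(a)[1]))
    putRow(a, i, 7.3 * scanValues(getRow(a, i)))
  pk2 <- pickPeaks2d(a, 3, noise = 7.3, calF1 = cal)
  m2 <- pk2[which.max(pk2$intensity), ]
  expect_equal(m2$f1_hz, main$f1_hz, tolerance = 1e-9)
  expect_equal(m2$f2_hz, main$f2_hz, tolerance = 1e-9)
  expect_equal(m2$intensity, 7.3 * main$intensity, tolerance = 1e-9)
})

test_that("precursor-m/z scatter across fragments is smaller in absorption mode", {
  # one precursor, six fragments on F2 bins, realistic noise: the standard
  # deviation of the measured precursor m/z across fragments (the paper-style
  # 6 vs 38 mDa comparison) must be strictly smaller in absorption mode
  B <- 15; off <- 150000
  acq <- simpleAcq(n1 = 512L, n2 = 2048L, off = off)
  frs <- lapply(c(160L, 300L, 480L, 620L, 790L, 950L), function(b)
    c(mz = onBinMz(b, f2Step(acq)), charge = 1, efficiency = 1 / 6))
  prs <- list(precursorSpec(592.29182, fragments = frs))
  sim <- generateDataset2d(simConfig(acq, prs, tau = 2e-4,
                                     noiseSigma = 0.08, seed = 11L))
  cal <- theoreticalCalibration(B)
  a <- absorption2d(sim$dataset, phaseFunction2d(),
                    apodF2 = apodizationSpec("kv_asymmetric_sqrt_fall"),
                    apodF1 = apodizationSpec("sine_bell"),
                    zerofillF1 = 2L, backing = "memory")
  m <- magnitude2d(sim$dataset,
                   apodF2 = apodizationSpec("sine_bell"),
                   apodF1 = apodizationSpec("sine_bell"),
                   zerofillF1 = 2L, backing = "memory")
  centroids <- function(d) {
    f1ax <- rowAxis(d)
    vapply(seq_len(nrow(sim$truth)), function(tt) {
      tr <- sim$truth[tt, ]
      j <- which.min(abs(axisValues(colAxis(d)) - tr$nu2_hz))
      cs <- scanValues(getCol(d, j))
      ctr <- which.min(abs(axisValues(f1ax) - tr$nu1_hz))
      i <- apexNear(cs, ctr, 25L)
      freqToMz(cal, parabFreq(cs, i, f1ax) + off)
    }, 0)
  }
  expect_lt(stats::sd(centroids(a)), stats::sd(centroids(m)))
})
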