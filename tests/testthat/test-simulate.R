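test_that("fragment amplitude is cosine-modulated at the precursor modulation frequency", {
  acq <- simpleAcq(n1 = 32L, n2 = 256L)
  cfg <- onBinSim(acq, b1 = 6L, b2 = 80L, efficiency = 1, tau = 1)
  sim <- generateDataset2d(cfg)
  # oracle: per-t1 fragment peak height from a plain fft of each row, then a
  # second fft of the height series; its maximum must sit at the bin nearest
  # the modulation frequency
  heights <- vapply(seq_len(32L), function(i) {
    Mod(stats::fft(scanValues(getRow(sim$dataset, i))))[81L]
  }, 0)
  amp1 <- Mod(stats::fft(heights - mean(heights)))[1:16]
  expect_identical(which.max(amp1), 7L)   # bin 6, 1-based
  expect_equal(sim$truth$nu1_hz, 6 * f1Step(acq), tolerance = 1e-9)
})

test_that("empty precursor list gives an all-zero grid; fixed seed reproduces bits", {
  acq <- simpleAcq(n1 = 8L, n2 = 64L)
  empty <- generateDataset2d(simConfig(acq, list(), tau = 1e-3))
  for (i in 1:8) expect_identical(scanValues(getRow(empty$dataset, i)),
                                  numeric(64))
  expect_identical(nrow(empty$truth), 0L)

  cfg <- onBinSim(acq, b1 = 2L, b2 = 20L, noiseSigma = 0.5, seed = 42L)
  g1 <- generateDataset2d(cfg)
  g2 <- generateDataset2d(cfg)
  for (i in 1:8) expect_identical(scanValues(getRow(g1$dataset, i)),
                                  scanValues(getRow(g2$dataset, i)))
})

test_that("unfragmented precursor intensity lands on the autocorrelation line", {
  acq <- simpleAcq(n1 = 16L, n2 = 128L, off = 1e5)
  pm <- onBinMz(40L, f2Step(acq))   # precursor visible in the F2 window
  pr <- precursorSpec(pm, fragments = list(
    c(mz = onBinMz(20L, f2Step(acq)), charge = 1, efficiency = 0.3)))
  sim <- generateDataset2d(simConfig(acq, list(pr), tau = 1e-3))
  self <- sim$truth[sim$truth$fragment_mz == sim$truth$precursor_mz, ]
  expect_identical(nrow(self), 1L)
  expect_equal(self$amplitude, 0.7, tolerance = 1e-12)
})

test_that("white noise has the configured scale; proportional noise leaves zeros", {
  acq <- simpleAcq(n1 = 128L, n2 = 1024L)   # >= 1e5 points
  zero <- generateDataset2d(simConfig(acq, list(), tau = 1e-3))$dataset
  addNoise(zero, sigma = 1, seed = 5L)
  vals <- unlist(lapply(1:128, function(i) scanValues(getRow(zero, i))))
  expect_equal(stats::sd(vals), 1, tolerance = 0.02)

  zero2 <- generateDataset2d(simConfig(acq, list(), tau = 1e-3))$dataset
  addNoise(zero2, sigma = 0, scintFraction = 0.5, seed = 5L)
  expect_identical(scanValues(getRow(zero2, 3L)), numeric(1024))

  # sigma = 0, scint = 0 leaves the grid untouched
  cfg <- onBinSim(acq, b1 = 10L, b2 = 100L)
  g <- generateDataset2d(cfg)$dataset
  before <- scanValues(getRow(g, 2L))
  addNoise(g, 0, 0)
  expect_identical(scanValues(getRow(g, 2L)), before)
})

test_that("doubling a fragment efficiency doubles its 2D peak intensity", {
  acq <- simpleAcq(n1 = 32L, n2 = 256L)
  peakInt <- function(eff) {
    # negligible damping: on-bin lines are exactly orthogonal, so the
    # self-fragment line cannot leak into the measured bin
    cfg <- onBinSim(acq, b1 = 6L, b2 = 60L, efficiency = eff, tau = 1e3)
    sim <- generateDataset2d(cfg)
    a <- absorption2d(sim$dataset, phaseFunction2d(),
                      apodF2 = apodizationSpec("none"),
                      apodF1 = apodizationSpec("none"), backing = "memory")
    scanValues(getRow(a, 7L))[61L]
  }
  expect_equal(peakInt(0.5) / peakInt(0.25), 2, tolerance = 1e-6)
})

test_that("out-of-window frequencies and bad efficiencies are rejected", {
  acq <- simpleAcq(n1 = 16L, n2 = 128L)
  tooFast <- precursorSpec(mzFromFrequency(3e5, 15))  # above 250 kHz band
  expect_error(generateDataset2d(simConfig(acq, list(tooFast), tau = 1e-3)),
               "configuration error")
  expect_error(precursorSpec(500, fragments = list(
    c(mz = 250, charge = 1, efficiency = -0.1))), "validation error")
  expect_error(precursorSpec(500, fragments = list(
    c(mz = 250, charge = 1, efficiency = 1.5))), "validation error")
})
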