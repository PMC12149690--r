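lay <- builtinLayout()

vial1Roi <- function(diameter = 18, slices = 2:4) {
  circleRoi(0, 0, diameter, slices, "vial1")
}

vial1Mean <- function(series, ...) {
  m <- measureVialAdc(series, lay, ...)
  m$mean_adc[m$vial_id == 1]
}

test_that("noiseless synthesis follows the mono-exponential closed form", {
  cfg <- tinyConfig()
  ser <- simulatePhantomSeries(lay, cfg)
  phys <- decodeSignal(ser)
  mid <- centralSlices(dim(ser)[3], 1)
  ctr <- dim(ser)[1:2] %/% 2
  s <- phys[ctr[1], ctr[2], mid, ]
  # b = 0 voxel inside vial 1 carries s0 exactly
  expect_identical(s[1], 1000)
  # ratio oracle: S(b)/S(0) = exp(-b * ADC)
  expect_equal(s / s[1], exp(-bValues(ser) * 1.109e-3), tolerance = 1e-12)
})

test_that("SNR calibration yields the target empirical SNR at b = 0", {
  cfg <- tinyNoisyConfig(seed = 7L)
  ser <- simulatePhantomSeries(lay, cfg)
  vol <- decodeSignal(ser)[, , , 1]  # b = 0
  # uniform background-free region well inside vial 1
  inp <- dwiQA:::circleFootprint(dim(vol), voxelSize(ser), 0, 0, 9)
  vals <- c(vol[, , 2][inp], vol[, , 3][inp], vol[, , 4][inp])
  snr <- mean(vals) / sd(vals)
  expect_gt(snr, 75 * 0.9)
  expect_lt(snr, 75 * 1.1)
})

test_that("identical seeds reproduce series; repetitions differ", {
  cfg <- tinyNoisyConfig(seed = 3L)
  a1 <- simulatePhantomSeries(lay, cfg, repetition = 1L)
  a2 <- simulatePhantomSeries(lay, cfg, repetition = 1L)
  b1 <- simulatePhantomSeries(lay, cfg, repetition = 2L)
  expect_identical(a1@signal, a2@signal)
  expect_false(identical(a1@signal, b1@signal))
  # and the global RNG state is left untouched
  set.seed(99); before <- .Random.seed
  invisible(simulatePhantomSeries(lay, cfg))
  expect_identical(.Random.seed, before)
})

test_that("study structure has one series per scanner/day/repetition", {
  cfg <- tinyConfig()
  study <- simulateStudy(lay, cfg, scanners = c("A", "B", "C"),
                         days = 2, repetitions = 4)
  expect_length(study, 24L)
  expect_identical(study[["B_d2_r3"]]@scannerId, "B")
  expect_identical(study[["B_d2_r3"]]@day, 2L)
  expect_identical(study[["B_d2_r3"]]@repetition, 3L)
  # zero bias + no noise: scanners are voxel-identical
  expect_identical(study[["A_d1_r1"]]@signal, study[["C_d1_r1"]]@signal)
})

test_that("scanner bias propagates exactly through the noiseless fit", {
  cfg <- tinyConfig(scannerBiasPercent = c(A = 1, B = 0))
  serA <- simulatePhantomSeries(lay, cfg, scannerId = "A")
  serB <- simulatePhantomSeries(lay, cfg, scannerId = "B")
  expect_equal(vial1Mean(serA), 1.109 * 1.01, tolerance = 1e-9)
  expect_equal(vial1Mean(serB), 1.109, tolerance = 1e-9)
})

test_that("session drift scales the fitted ADC per day", {
  cfg <- tinyConfig(sessionDriftPercent = 2)
  d1 <- simulatePhantomSeries(lay, cfg, day = 1L)
  d2 <- simulatePhantomSeries(lay, cfg, day = 2L)
  expect_equal(vial1Mean(d2) / vial1Mean(d1), 1.02, tolerance = 1e-9)
})

test_that("noise-free synthesis refits the generating ADC exactly", {
  cfg <- tinyConfig(rescaleSlope = 3.5, rescaleIntercept = -20)
  m <- measureVialAdc(simulatePhantomSeries(lay, cfg), lay)
  expect_equal(m$mean_adc, referenceAdc(lay, m$vial_id), tolerance = 1e-9)
  expect_equal(m$sd_adc, rep(0, 13), tolerance = 1e-9)
})

test_that("fitted-ADC bias magnitude is non-increasing in SNR", {
  snrs <- c(15, 40, 100)
  med <- vapply(snrs, function(snr) {
    biases <- vapply(1:7, function(s) {
      ser <- simulatePhantomSeries(lay, tinyNoisyConfig(seed = 100 + s,
                                                        snrB0 = snr))
      percentBias(vial1Mean(ser), 1.109)
    }, numeric(1))
    median(abs(biases))
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
})

test_that("vial footprints outside the matrix raise a geometry error", {
  cfg <- simConfig(noiseModel = "none", matrixSize = c(40L, 40L, 3L),
                   voxelSize = c(2, 2, 8))
  expect_error(simulatePhantomSeries(lay, cfg), "outside the image matrix")
})

test_that("organ volumes recover their generating ADC and flag truncation", {
  cfg <- simConfig(noiseModel = "none", matrixSize = c(64L, 64L, 5L),
                   voxelSize = c(3, 3, 6))
  res <- simulateOrganVolume(list(
    list(label = "brain", adc = 0.83, center_mm = c(-20, 0, 0),
         semiaxes_mm = c(35, 45, 12)),
    list(label = "clipped", adc = 1.5, center_mm = c(65, 0, 10),
         semiaxes_mm = c(18, 18, 10))), cfg)
  map <- fitAdcMap(res$series)
  stBrain <- organMaskStats(map, res$masks$brain, "brain")
  stClip <- organMaskStats(map, res$masks$clipped, "clipped")
  expect_equal(stBrain$mean_adc, 0.83, tolerance = 1e-9)
  expect_true(stBrain$contained)
  expect_false(stClip$contained)
  expect_false(attr(res$masks$brain, "truncated"))
  expect_true(attr(res$masks$clipped, "truncated"))
})

test_that("overlapping organ masks are rejected", {
  cfg <- simConfig(noiseModel = "none", matrixSize = c(32L, 32L, 3L),
                   voxelSize = c(4, 4, 8))
  specs <- list(
    list(label = "a", adc = 1, center_mm = c(0, 0, 0),
         semiaxes_mm = c(20, 20, 8)),
    list(label = "b", adc = 2, center_mm = c(10, 0, 0),
         semiaxes_mm = c(20, 20, 8)))
  expect_error(simulateOrganVolume(specs, cfg), "overlap")
})

test_that("noisy organ means are centered on the generating ADC", {
  means <- vapply(1:20, function(s) {
    cfg <- simConfig(noiseModel = "rician", snrB0 = 30, seed = 200L + s,
                     matrixSize = c(48L, 48L, 3L), voxelSize = c(4, 4, 8))
    res <- simulateOrganVolume(list(
      list(label = "organ", adc = 0.83, center_mm = c(0, 0, 0),
           semiaxes_mm = c(50, 50, 10))), cfg,
      repetition = s)
    organMaskStats(fitAdcMap(res$series), res$masks$organ)$mean_adc
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  # centered on truth within Monte-Carlo error (small Rician bias allowed)
  expect_lt(abs(mean(means) - 0.83), max(4 * se, 0.01))
})
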