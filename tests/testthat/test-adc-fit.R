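test_that("rescale decode/encode are exact inverses", {
  expect_equal(applyRescale(100, 1, 0), 100)
  expect_equal(applyRescale(100, 2.5, 10), 260)
  x <- runif(50, -5, 500)
  expect_equal(applyRescale(encodeRescale(x, 3.7, -12), 3.7, -12), x,
               tolerance = 1e-15)
  expect_error(applyRescale(1, 0, 0), "non-zero")
  expect_error(encodeRescale(1, 0, 0), "non-zero")
})

test_that("two-point ADC matches the log-ratio closed form", {
  expect_equal(twoPointAdc(1000, 1000, 150, 500), 0)
  # S0 = 1000, ADC = 1.0 um2/ms: S(150) = 860.708, S(500) = 606.531
  expect_equal(twoPointAdc(860.7, 606.5, 150, 500), 1.000, tolerance = 1e-3)
  expect_equal(twoPointAdc(1000 * exp(-0.15), 1000 * exp(-0.5), 150, 500),
               1, tolerance = 1e-12)
  expect_error(twoPointAdc(1000, 0, 150, 500), "positive")
  expect_error(twoPointAdc(1000, 500, 150, 150), "differ")
})

test_that("map fit with two b-values equals the scalar closed form", {
  set.seed(42)
  vols <- list(array(runif(60, 100, 1000), c(5, 4, 3)),
               array(runif(60, 10, 500), c(5, 4, 3)))
  ser <- manualSeries(vols, c(150, 500))
  map <- fitAdcMap(ser)
  oracle <- twoPointAdc(vols[[1]], vols[[2]], 150, 500)
  expect_equal(adcValues(map), oracle, tolerance = 1e-12)
  map2 <- fitAdcMap(ser, method = "two_point")
  expect_equal(adcValues(map2), oracle, tolerance = 1e-12)
})

test_that("log-linear fit equals brute-force normal equations", {
  set.seed(7)
  b <- c(0, 150, 500, 900, 2000)
  d <- c(4L, 3L, 2L)
  vols <- lapply(b, function(bb) array(exp(runif(prod(d), 2, 7)), d))
  ser <- manualSeries(vols, b, slope = 2, intercept = 5)
  map <- fitAdcMap(ser)
  X <- cbind(1, b)
  for (i in sample(prod(d), 10)) {
    beta <- solve(t(X) %*% X, t(X) %*% log(vapply(vols, function(v) v[i],
                                                  numeric(1))))
    expect_equal(adcValues(map)[i], -beta[2] * 1000, tolerance = 1e-10)
  }
})

test_that("ADC is invariant to signal scale and equivariant in b", {
  set.seed(11)
  b <- c(0, 500, 900, 2000)
  d <- c(4L, 4L, 2L)
  vols <- lapply(b, function(bb) array(exp(runif(prod(d), 2, 7)), d))
  base <- adcValues(fitAdcMap(manualSeries(vols, b)))
  scaled <- adcValues(fitAdcMap(manualSeries(lapply(vols, `*`, 37.5), b)))
  expect_equal(scaled, base, tolerance = 1e-12)
  bScaled <- adcValues(fitAdcMap(manualSeries(vols, b * 2)))
  expect_equal(bScaled, base / 2, tolerance = 1e-12)
})

test_that("constant signal across b fits ADC = 0", {
  vols <- lapply(1:3, function(i) array(250, c(3, 3, 2)))
  map <- fitAdcMap(manualSeries(vols, c(0, 500, 1000)))
  expect_equal(adcValues(map), array(0, c(3, 3, 2)))
})

test_that("signal at or below the floor invalidates the voxel", {
  vols <- list(array(1000, c(2, 2, 1)), array(300, c(2, 2, 1)))
  vols[[2]][1, 1, 1] <- 0
  map <- fitAdcMap(manualSeries(vols, c(0, 800)))
  expect_false(validMask(map)[1, 1, 1])
  expect_true(all(validMask(map)[-1]))
  expect_true(is.na(adcValues(map)[1, 1, 1]))
})

test_that("b-subset selection enforces the series contents", {
  vols <- lapply(c(0, 150, 500), function(bb)
    array(1000 * exp(-bb * 1.2e-3), c(2, 2, 1)))
  ser <- manualSeries(vols, c(0, 150, 500))
  expect_error(fitAdcMap(ser, bSubset = c(150, 900)), "not present")
  expect_error(fitAdcMap(ser, bSubset = 500), "at least 2")
  map <- fitAdcMap(ser, bSubset = c(150, 500))
  expect_equal(bValues(map), c(150, 500))
  expect_equal(adcValues(map)[1], 1.2, tolerance = 1e-12)
})

test_that("weighted and uniform fits agree on noiseless data", {
  lay <- builtinLayout()
  ser <- simulatePhantomSeries(lay, tinyConfig())
  m1 <- fitAdcMap(ser)
  m2 <- fitAdcMap(ser, weighted = TRUE)
  v <- validMask(m1)
  expect_equal(adcValues(m2)[v], adcValues(m1)[v], tolerance = 1e-9)
})

test_that("negative fits are retained but clampable", {
  vols <- list(array(500, c(2, 2, 1)), array(600, c(2, 2, 1)))  # rising signal
  map <- fitAdcMap(manualSeries(vols, c(0, 1000)))
  expect_true(all(adcValues(map) < 0))
  expect_true(all(validMask(map)))
  expect_equal(adcValues(clampNegativeAdc(map)), array(0, c(2, 2, 1)))
})

test_that("map comparison reports signed percent difference of ROI means", {
  mapA <- manualAdcMap(1.1, c(6L, 6L, 3L))
  roi <- circleRoi(0, 0, 4, 1:3)
  expect_equal(compareAdcMaps(mapA, mapA, roi)$percent_diff, 0)
  mapB <- mapA; mapB@adc <- mapA@adc * 1.021
  expect_equal(compareAdcMaps(mapB, mapA, roi)$percent_diff, 2.1,
               tolerance = 1e-9)
  # unit harmonization: a um2/s rendering of the same map compares equal
  mapS <- convertAdcUnits(mapA, "um2/s")
  expect_equal(adcUnits(mapS), "um2/s")
  expect_equal(compareAdcMaps(mapS, mapA, roi)$percent_diff, 0)
  mapC <- manualAdcMap(1, c(5L, 5L, 3L))
  expect_error(compareAdcMaps(mapA, mapC, roi), "different grids")
})
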