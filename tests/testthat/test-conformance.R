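lay <- builtinLayout()

test_that("percent bias is signed and guarded", {
  expect_equal(percentBias(1.109, 1.109), 0)
  expect_equal(percentBias(1.209, 1.109), 100 * 0.1 / 1.109)
  expect_equal(percentBias(1.0, 1.109), -100 * 0.109 / 1.109)
  expect_error(percentBias(1, 0), "positive")
})

test_that("cvPercent uses the sample SD and validates input", {
  expect_equal(cvPercent(c(1.11, 1.11, 1.11)), 0)
  expect_equal(cvPercent(c(1.0, 1.1)), 100 * sd(c(1, 1.1)) / 1.05)
  expect_equal(cvPercent(c(1.0, 1.1)), 6.734, tolerance = 1e-4)
  expect_error(cvPercent(1.0), "at least 2")
  expect_error(cvPercent(c(-1, 1)), "zero mean")
})

test_that("repeatability returns wSD, RC = 2.77 wSD, and CV", {
  expect_equal(repeatability(rep(1.109, 4)), list(wSD = 0, RC = 0, CV = 0))
  # wSD 0.00433 at mean ~1.109 gives RC ~0.0120 and CV ~0.39%
  x <- c(-1.5, -0.5, 0.5, 1.5)
  x <- 1.109 + x * 0.00433 / sd(x)
  r <- repeatability(x)
  expect_equal(r$wSD, 0.00433, tolerance = 1e-10)
  expect_equal(r$RC, 2.77 * 0.00433, tolerance = 1e-10)
  expect_equal(r$RC, 0.0120, tolerance = 1e-3)
  expect_equal(r$CV, 100 * 0.00433 / mean(x), tolerance = 1e-10)
  expect_error(repeatability(1.1), "at least 2")
  # n = 2 between-session form reduces to |x1 - x2| / sqrt(2)
  r2 <- repeatability(c(1.10, 1.12))
  expect_equal(r2$wSD, 0.02 / sqrt(2))
})

test_that("RC/CV identities hold on random inputs", {
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(2:8, 1), mean = runif(1, 0.5, 2), sd = 0.05)
    r <- repeatability(x)
    expect_equal(r$wSD, sd(x), tolerance = 1e-12)
    expect_equal(r$RC, 2.77 * (r$CV / 100) * mean(x), tolerance = 1e-12)
    expect_equal(cvPercent(x), 100 * sd(x) / mean(x), tolerance = 1e-12)
  }
})

test_that("linearity matches brute-force normal equations", {
  ref <- c(1.109, 0.817, 0.579, 0.380, 0.220, 0.110)
  lin <- linearity(ref, ref)
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$slope, 1)
  expect_equal(lin$intercept, 0, tolerance = 1e-12)
  lin2 <- linearity(1.02 * ref, ref)
  expect_equal(lin2$slope, 1.02)
  expect_equal(lin2$r_squared, 1)
  set.seed(21)
  meas <- ref * (1 + rnorm(6, 0, 0.02))
  lin3 <- linearity(meas, ref)
  X <- cbind(1, ref)
  beta <- solve(t(X) %*% X, t(X) %*% meas)
  expect_equal(lin3$intercept, beta[1], tolerance = 1e-10)
  expect_equal(lin3$slope, beta[2], tolerance = 1e-10)
  ss_res <- sum((meas - X %*% beta)^2)
  ss_tot <- sum((meas - mean(meas))^2)
  expect_equal(lin3$r_squared, 1 - ss_res / ss_tot, tolerance = 1e-10)
  expect_error(linearity(c(1, 2), c(1, 2)), "distinct")
})

test_that("precision CV is the within-ROI spatial CV", {
  map <- manualAdcMap(1.2, c(6L, 6L, 3L))
  expect_equal(precisionCv(map, circleRoi(0, 0, 4, 2L)), 0)
  set.seed(3)
  d <- c(6L, 6L, 1L)
  vals <- array(rnorm(prod(d), 1.1, 0.05), d)
  map2 <- manualAdcMap(vals, d)
  roi <- circleRoi(0, 0, 100, 1L)
  expect_equal(precisionCv(map2, roi), 100 * sd(vals) / mean(vals),
               tolerance = 1e-12)
})

test_that("SNR at b = 0 is mean over SD with a degenerate-noise flag", {
  mk <- function(b0vals) {
    v0 <- array(b0vals, c(2, 1, 1))
    manualSeries(list(v0, v0 * exp(-0.5)), c(0, 500))
  }
  s <- mk(c(800 - 10 / sqrt(2), 800 + 10 / sqrt(2)))  # mean 800, sd 10
  res <- snrB0(s, circleRoi(0, 0, 10, 1L))
  expect_equal(res$snr, 80, tolerance = 1e-12)
  expect_false(res$degenerate)
  res0 <- snrB0(mk(c(800, 800)), circleRoi(0, 0, 10, 1L))
  expect_true(res0$degenerate)
  expect_identical(res0$snr, Inf)
  noB0 <- manualSeries(list(array(1, c(2, 1, 1)), array(0.5, c(2, 1, 1))),
                       c(150, 500))
  expect_error(snrB0(noB0, circleRoi(0, 0, 10, 1L)), "b = 0")
})

test_that("b-value dependence is zero for model-consistent data and finds a floored b", {
  ser <- simulatePhantomSeries(lay, tinyConfig())
  roi <- circleRoi(0, 0, 18, 2:4)
  dep <- bValueDependence(ser, roi)
  expect_lt(dep$max_dep_percent, 1e-9)
  # inject an additive noise floor; it perturbs the lowest-signal
  # (highest-b) images most, so the worst pair involves the top b-value
  sig <- ser@signal + 0.02 * 1000
  ser2 <- methods::new("DwiSeries", signal = sig, bValues = bValues(ser),
                       rescaleSlope = 1, rescaleIntercept = 0,
                       voxelSize = voxelSize(ser), scannerId = "T",
                       day = 1L, repetition = 1L, sequenceName = "manual")
  dep2 <- bValueDependence(ser2, roi)
  expect_true(2000 %in% dep2$spread_pair)
  expect_gt(dep2$pairwise_spread_percent, dep2$max_dep_percent)
  # pairwise ADCs equal the scalar two-point oracle on ROI-mean signals
  phys <- decodeSignal(ser2)
  inp <- dwiQA:::circleFootprint(dim(phys)[1:3], voxelSize(ser2), 0, 0, 9)
  sbar <- vapply(1:4, function(k)
    mean(c(phys[, , 2, k][inp], phys[, , 3, k][inp], phys[, , 4, k][inp])),
    numeric(1))
  b <- bValues(ser2)
  for (r in seq_len(nrow(dep2$table))) {
    i <- match(dep2$table$b1[r], b); j <- match(dep2$table$b2[r], b)
    expect_equal(dep2$table$adc_pair[r], twoPointAdc(sbar[i], sbar[j],
                                                     b[i], b[j]),
                 tolerance = 1e-12)
  }
  expect_error(bValueDependence(
    manualSeries(list(array(1, c(2, 2, 1)), array(0.5, c(2, 2, 1))),
                 c(0, 500)), roi), ">= 3")
})

test_that("a noiseless zero-bias study passes every computable test", {
  study <- batteryStudy(lay, tinyConfig())
  bat <- runQibaBattery(study, lay)
  expect_true(all(bat$passed))
  expect_match(bat$note[bat$test == "F"], "degenerate")
  # determinism: identical inputs give identical batteries
  expect_identical(runQibaBattery(study, lay), bat)
})

test_that("a +5% scanner bias fails exactly the accuracy test", {
  cfg <- tinyConfig(scannerBiasPercent = c(A = 5))
  bat <- runQibaBattery(batteryStudy(lay, cfg, scanner = "A"), lay)
  expect_false(bat$passed[bat$test == "A"])
  expect_true(all(bat$passed[bat$test != "A"]))
})

test_that("a missing second day reports N/A for the between-session test", {
  bat <- runQibaBattery(batteryStudy(lay, tinyConfig(), day2 = FALSE), lay)
  expect_true(all(is.na(bat$passed[bat$test == "C"])))
  expect_true(all(is.na(bat$value[bat$test == "C"])))
  expect_match(bat$note[bat$test == "C"][1], "N/A")
  expect_true(all(bat$passed[!bat$test %in% "C"]))
})

test_that("too few same-day repetitions raise an error naming test B", {
  study <- batteryStudy(lay, tinyConfig())["A_d1_r1"]
  expect_error(runQibaBattery(study, lay), "test B")
})
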