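lay <- builtinLayout()

test_that("grand row is the unweighted mean of per-vial values", {
  g <- grandRowSummary(c(1, 2, 3), c(0.1, 0.2, 0.9))
  expect_equal(unname(g["bias_percent"]), 2)
  expect_equal(unname(g["cv_percent"]), 0.4)
})

test_that("identical scanners give zero inter-scanner CV for every vial", {
  meas <- expand.grid(scanner = c("A", "B", "C"), vial_id = 1:13,
                      repetition = 1:4, stringsAsFactors = FALSE)
  meas$mean_adc <- referenceAdc(lay, meas$vial_id)
  s <- multiStudySummary(meas, lay)
  expect_equal(s$per_vial$cv_percent, rep(0, 13))
  expect_equal(s$per_vial$bias_percent, rep(0, 13))
  expect_equal(unname(s$grand), c(0, 0))
})

test_that("a two-scanner two-vial toy matches spreadsheet arithmetic", {
  meas <- data.frame(
    scanner = rep(c("A", "A", "B", "B"), each = 2),
    vial_id = rep(c(1L, 4L), 4),
    repetition = rep(1:2, each = 2, times = 2),
    mean_adc = c(1.10, 0.80,   # A rep1: vial1, vial4
                 1.12, 0.82,   # A rep2
                 1.14, 0.84,   # B rep1
                 1.16, 0.86))  # B rep2
  s <- multiStudySummary(meas, lay)
  # intra-scanner means
  expect_equal(s$per_scanner$mean_adc,
               c(1.11, 0.81, 1.15, 0.85))
  biasA1 <- 100 * (1.11 - 1.109) / 1.109
  biasB1 <- 100 * (1.15 - 1.109) / 1.109
  biasA4 <- 100 * (0.81 - 0.817) / 0.817
  biasB4 <- 100 * (0.85 - 0.817) / 0.817
  expect_equal(s$per_vial$bias_percent,
               c(mean(c(biasA1, biasB1)), mean(c(biasA4, biasB4))))
  expect_equal(s$per_vial$cv_percent,
               c(100 * sd(c(1.11, 1.15)) / mean(c(1.11, 1.15)),
                 100 * sd(c(0.81, 0.85)) / mean(c(0.81, 0.85))))
  expect_equal(unname(s$grand["bias_percent"]),
               mean(s$per_vial$bias_percent))
})

test_that("mismatched vial sets across scanners are rejected", {
  meas <- data.frame(scanner = c("A", "A", "B"), vial_id = c(1L, 2L, 1L),
                     repetition = 1L, mean_adc = 1)
  expect_error(multiStudySummary(meas, lay), "different vial sets")
  one <- data.frame(scanner = "A", vial_id = 1L, repetition = 1L,
                    mean_adc = 1)
  expect_error(multiStudySummary(one, lay), ">= 2 scanners")
})

test_that("simulated per-scanner biases are recovered by the aggregation", {
  cfg <- tinyConfig(scannerBiasPercent = c(A = -1, B = 0, C = 2))
  study <- simulateStudy(lay, cfg, scanners = c("A", "B", "C"),
                         days = 1, repetitions = 2)
  meas <- do.call(rbind, lapply(study, measureVialAdc, layout = lay))
  s <- multiStudySummary(meas, lay)
  perScanner <- tapply(s$per_scanner$bias_percent, s$per_scanner$scanner,
                       mean)
  expect_equal(as.vector(perScanner[c("A", "B", "C")]), c(-1, 0, 2),
               tolerance = 1e-6)
  # inter-scanner CV approaches the bias-implied CV in the noiseless limit
  implied <- 100 * sd(1.109 * c(0.99, 1, 1.02)) / mean(1.109 * c(0.99, 1, 1.02))
  expect_equal(s$per_vial$cv_percent[1], implied, tolerance = 1e-6)
})

test_that("organ summary handles missing days and containment", {
  meas <- data.frame(
    scanner = c("A", "A", "B", "C", "C"),
    day = c(1, 2, 1, 1, 2),
    organ = "brain",
    mean_adc = c(0.80, 0.80, 0.85, 0.90, 0.95),
    contained = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  s <- organLevelSummary(meas)
  ps <- s$per_scanner
  expect_equal(ps$cv_bs_percent[ps$scanner == "A"], 0)          # identical days
  expect_true(is.na(ps$cv_bs_percent[ps$scanner == "B"]))       # day 1 only
  expect_true(is.na(ps$cv_bs_percent[ps$scanner == "C"]))       # day 2 excluded
  is1 <- s$inter_scanner
  expect_equal(is1$n_scanners, 3L)
  expect_equal(is1$mean_adc, mean(c(0.80, 0.85, 0.90)))
  expect_equal(is1$cv_percent, cvPercent(c(0.80, 0.85, 0.90)))
})

test_that("injected inter-scanner offsets give the closed-form organ CV", {
  specs <- list(list(label = "organ", adc = 0.83, center_mm = c(0, 0, 0),
                     semiaxes_mm = c(50, 50, 10)))
  offs <- c(A = 0.98, B = 1.00, C = 1.03)
  rows <- lapply(names(offs), function(sc) {
    cfg <- simConfig(noiseModel = "none", matrixSize = c(48L, 48L, 3L),
                     voxelSize = c(4, 4, 8))
    res <- simulateOrganVolume(lapply(specs, function(s) {
      s$adc <- s$adc * offs[[sc]]; s
    }), cfg, scannerId = sc)
    st <- organMaskStats(fitAdcMap(res$series), res$masks$organ, "organ")
    data.frame(scanner = sc, day = 1, organ = "organ",
               mean_adc = st$mean_adc, contained = st$contained)
  })
  s <- organLevelSummary(do.call(rbind, rows))
  expect_equal(s$inter_scanner$cv_percent, cvPercent(0.83 * offs),
               tolerance = 1e-9)
})
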