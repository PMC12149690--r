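# Shared fixtures: small grids keep the unit tests fast; the acceptance
# tests use the generator's default study conditions.

# Noiseless phantom config on a coarse grid that still contains the full
# vial footprint (FOV 168 mm > 2 * (66 + 15) mm).
tinyConfig <- function(...) {
  simConfig(noiseModel = "none", matrixSize = c(84L, 84L, 5L),
            voxelSize = c(2, 2, 8), ...)
}

# Rician-noise variant of the same grid.
tinyNoisyConfig <- function(seed = 1L, snrB0 = 75, ...) {
  simConfig(noiseModel = "rician", snrB0 = snrB0, seed = as.integer(seed),
            matrixSize = c(84L, 84L, 5L), voxelSize = c(2, 2, 8), ...)
}

# Hand-built ADC map with known voxel values (uniform by default).
manualAdcMap <- function(values, dim3 = c(4L, 4L, 3L), voxelSize = c(1, 1, 1),
                         valid = NULL) {
  a <- array(values, dim = dim3)
  if (is.null(valid)) valid <- array(TRUE, dim = dim3)
  new("AdcMap", adc = a, validMask = valid,
      bValuesUsed = c(0, 1000), fitMethod = "loglinear_lsq",
      units = "um2/ms", voxelSize = voxelSize,
      provenance = list(scanner_id = "T", day = 1L, repetition = 1L,
                        sequence_name = "manual", signal_floor = 0,
                        weighted = FALSE))
}

# Hand-built series with explicit per-volume signal arrays (stored = phys).
manualSeries <- function(vols, bValues, voxelSize = c(1, 1, 1),
                         slope = 1, intercept = 0) {
  d <- dim(vols[[1]])
  arr <- array(NA_real_, dim = c(d, length(vols)))
  for (k in seq_along(vols)) arr[, , , k] <- vols[[k]]
  new("DwiSeries", signal = encodeRescale(arr, slope, intercept),
      bValues = bValues, rescaleSlope = slope, rescaleIntercept = intercept,
      voxelSize = voxelSize, scannerId = "T", day = 1L, repetition = 1L,
      sequenceName = "manual")
}

# Day-1 x 4 repetitions (+ optional day-2 first) study for one scanner.
batteryStudy <- function(layout, config, scanner = "A", day2 = TRUE) {
  study <- list()
  for (r in 1:4)
    study[[sprintf("%s_d1_r%d", scanner, r)]] <-
      simulatePhantomSeries(layout, config, scannerId = scanner,
                            day = 1L, repetition = r)
  if (day2)
    study[[sprintf("%s_d2_r1", scanner)]] <-
      simulatePhantomSeries(layout, config, scannerId = scanner,
                            day = 2L, repetition = 1L)
  study
}
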