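## High-level workflows tying the modules together, plus report writers.

## small rolling hash (config fingerprint for the provenance log)
textHash <- function(text) {
  h <- 5381
  for (b in utf8ToInt(text)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

configFingerprint <- function(config) {
  textHash(paste(
    paste(config@bValues, collapse = ","), config@s0, config@snrB0,
    config@noiseModel, paste(names(config@scannerBiasPercent),
                             config@scannerBiasPercent, collapse = ","),
    config@sessionDriftPercent, paste(config@voxelSize, collapse = ","),
    paste(config@matrixSize, collapse = ","), config@seed,
    config@rescaleSlope, config@rescaleIntercept, config@shadingPercent
  ))
}

writeProvenanceLog <- function(path, config, extra = character(0)) {
  kv <- c(
    package = "dwiQA",
    package_version = as.character(utils::packageVersion("dwiQA")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = configFingerprint(config),
    seed = config@seed,
    noise_model = config@noiseModel,
    snr_b0 = config@snrB0,
    b_values = paste(config@bValues, collapse = " "),
    fit_weighting = "uniform_log_ols",
    cv_p_interpretation = "spatial_single_repetition",
    dep_b_reference = "all_b_fit_of_roi_mean_signal",
    extra
  )
  writeFlatConfig(kv, path, header = "dwiQA run provenance")
  invisible(path)
}

#' Simulate a multi-scanner phantom study and run the full QA analysis
#'
#' End-to-end convenience workflow: simulates a (scanner, day, repetition)
#' phantom study, runs the conformance battery per scanner, aggregates the
#' day-1 measurements into the multi-scanner per-vial bias/CV summary, and
#' (optionally) writes tidy CSV reports plus a provenance log recording the
#' analysis switches in force.
#'
#' @param layout a [PhantomLayout-class].
#' @param config a [SimulationConfig-class].
#' @param scanners scanner identifiers.
#' @param days,repetitions study structure.
#' @param bSubset optional b-subset for fitting.
#' @param roiDiameterMm battery ROI diameter (see [runQibaBattery()]).
#' @param outDir optional output directory for CSV/JSON reports.
#' @return list with \code{study} (the series), \code{battery} (named list
#'   of per-scanner conformance tables), \code{summary}
#'   (from [multiStudySummary()]), and \code{files} (paths written).
#' @export
runPhantomQa <- function(layout = builtinLayout(), config = simConfig(),
                         scanners = c("A", "B", "C"), days = 2L,
                         repetitions = 4L, bSubset = NULL,
                         roiDiameterMm = NULL, outDir = NULL) {
  study <- simulateStudy(layout, config, scanners = scanners, days = days,
                         repetitions = repetitions)
  sids <- vapply(study, function(s) s@scannerId, character(1))
  battery <- lapply(stats::setNames(scanners, scanners), function(sc)
    runQibaBattery(study[sids == sc], layout, bSubset = bSubset,
                   roiDiameterMm = roiDiameterMm))
  summ <- NULL
  if (length(scanners) >= 2) {
    day1 <- study[vapply(study, function(s) s@day, integer(1)) == 1L]
    meas <- do.call(rbind, lapply(day1, measureVialAdc, layout = layout,
                                  bSubset = bSubset,
                                  roiDiameterMm = roiDiameterMm))
    summ <- multiStudySummary(meas, layout)
  }
  files <- character(0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (sc in scanners) {
      f <- file.path(outDir, sprintf("conformance_%s.csv", sc))
      utils::write.csv(battery[[sc]], f, row.names = FALSE)
      files <- c(files, f)
    }
    if (!is.null(summ)) {
      pv <- summ$per_vial
      grand <- data.frame(vial_id = NA_integer_, reference_adc = NA_real_,
                          mean_adc = NA_real_,
                          bias_percent = summ$grand[["bias_percent"]],
                          cv_percent = summ$grand[["cv_percent"]])
      f <- file.path(outDir, "per_vial_summary.csv")
      utils::write.csv(rbind(pv, grand), f, row.names = FALSE)
      files <- c(files, f)
    }
    f <- file.path(outDir, "conformance_passfail.json")
    jsonlite::write_json(
      lapply(battery, function(tb)
        stats::setNames(as.list(tb$passed), paste(tb$test, tb$metric, sep = "_"))),
      f, auto_unbox = TRUE)
    files <- c(files, f)
    f <- file.path(outDir, "provenance.cfg")
    writeProvenanceLog(f, config,
                       c(scanners = paste(scanners, collapse = ","),
                         days = days, repetitions = repetitions,
                         b_subset = paste(if (is.null(bSubset)) "all" else bSubset,
                                          collapse = " ")))
    files <- c(files, f)
  }
  list(study = study, battery = battery, summary = summ, files = files)
}

#' Plot the central slice of an ADC map
#'
#' Basic diagnostic rendering: grayscale image of one slice with invalid
#' voxels blanked.
#'
#' @param x an [AdcMap-class].
#' @param y ignored.
#' @param slice slice index (default: central slice).
#' @param ... passed to [graphics::image()].
#' @return invisibly, the plotted matrix.
#' @export
setMethod("plot", signature(x = "AdcMap", y = "missing"),
          function(x, y, slice = NULL, ...) {
  if (is.null(slice)) slice <- centralSlices(dim(x@adc)[3], 1)
  m <- x@adc[, , slice]
  m[!x@validMask[, , slice]] <- NA
  graphics::image(t(m[nrow(m):1, ]), col = grDevices::gray.colors(128),
                  axes = FALSE, asp = dim(m)[1] / dim(m)[2],
                  main = sprintf("ADC map, slice %d (%s)", slice, x@units),
                  ...)
  invisible(m)
})
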