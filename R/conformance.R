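#' Signed percent bias against a reference value
#'
#' \eqn{100 (measured - reference) / reference}.
#'
#' @param measured,reference ADC values, um^2/ms; \code{reference} must be
#'   positive.
#' @return signed bias in percent.
#' @export
percentBias <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference ADC must be positive")
  100 * (measured - reference) / reference
}

#' Coefficient of variation in percent
#'
#' \code{100 * sd(values) / mean(values)} with the sample (n-1) SD. Used for
#' short-term and between-session repeatability and for inter-scanner
#' reproducibility.
#'
#' @param values at least two numeric values with non-zero mean.
#' @return CV in percent.
#' @export
cvPercent <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("CV requires at least 2 values")
  m <- mean(values)
  if (m == 0) stop("CV undefined for zero mean")
  100 * stats::sd(values) / m
}

#' Repeatability statistics from repeated measurements
#'
#' From a set of repetition means: the within-subject SD (\code{wSD}, sample
#' SD of the repetition means), the repeatability coefficient
#' \code{RC = 2.77 * wSD} (the bound expected to contain 95% of test-retest
#' differences), and \code{CV = 100 * wSD / mean}. The same formulas serve
#' the short-term (same-day repetitions) and between-session (first
#' measurements on consecutive days; with n = 2, \code{wSD = |x1 - x2| /
#' sqrt(2)}) variants.
#'
#' @param values numeric, >= 2 repetition means (um^2/ms).
#' @return list with \code{wSD}, \code{RC} (um^2/ms) and \code{CV} (%).
#' @export
repeatability <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("repeatability requires at least 2 repetitions")
  wSD <- stats::sd(values)
  list(wSD = wSD, RC = 2.77 * wSD, CV = 100 * wSD / mean(values))
}

#' Linearity of measured versus reference ADC
#'
#' Ordinary least-squares line of measured on reference across the phantom
#' vials, summarized by the coefficient of determination and the slope.
#'
#' @param measured,reference per-vial ADC values, um^2/ms; at least 3 vials
#'   with distinct reference values are required.
#' @return list with \code{r_squared}, \code{slope}, \code{intercept}.
#' @export
linearity <- function(measured, reference) {
  stopifnot(length(measured) == length(reference))
  if (length(unique(reference)) < 3)
    stop("linearity requires >= 3 distinct reference values")
  fit <- stats::lm(measured ~ reference)
  ssRes <- sum(stats::residuals(fit)^2)
  ssTot <- sum((measured - mean(measured))^2)
  list(r_squared = 1 - ssRes / ssTot,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Within-ROI spatial precision of a single repetition
#'
#' \code{100 * spatial SD / spatial mean} of the voxel ADC values inside the
#' ROI of one repetition — the single-measurement precision metric. (This
#' spatial reading is the one consistent with computing the metric from the
#' first repetition only; it is a documented interpretation.)
#'
#' @param map an [AdcMap-class] from a single repetition.
#' @param roi a single-ROI [RoiSet-class].
#' @return CV_P in percent.
#' @export
precisionCv <- function(map, roi) {
  st <- extractRoiStats(map, roi)
  if (nrow(st) != 1) stop("precisionCv expects a single ROI")
  if (st$n_pixels[1] < 2) stop("precision requires >= 2 valid voxels")
  100 * st$sd_adc[1] / st$mean_adc[1]
}

#' SNR of the b = 0 image within an ROI
#'
#' Mean over SD of the decoded b = 0 signal across the ROI voxels of one
#' repetition. A zero SD (noiseless data) is reported as infinite SNR with a
#' degeneracy flag rather than an error.
#'
#' @param series a [DwiSeries-class] containing a b = 0 volume.
#' @param roi a single-circle [RoiSet-class].
#' @return list with \code{snr}, \code{mean}, \code{sd}, \code{n_pixels},
#'   \code{degenerate}.
#' @export
snrB0 <- function(series, roi) {
  stopifnot(methods::is(series, "DwiSeries"), methods::is(roi, "RoiSet"))
  if (!any(series@bValues == 0)) stop("series has no b = 0 volume")
  k <- which(series@bValues == 0)[1]
  d <- dim(series@signal)[1:3]
  vol <- array(applyRescale(series@signal[, , , k, drop = FALSE],
                            series@rescaleSlope, series@rescaleIntercept),
               dim = d)
  cl <- roi@circles
  if (nrow(cl) != 1) stop("snrB0 expects a single circular ROI")
  inp <- circleMembership(d, series@voxelSize, cl$x_mm[1], cl$y_mm[1],
                          cl$diameter_mm[1] / 2)
  vals <- unlist(lapply(roi@slices, function(sl) vol[, , sl][inp]))
  m <- mean(vals); s <- stats::sd(vals)
  if (s == 0)
    list(snr = Inf, mean = m, sd = 0, n_pixels = length(vals),
         degenerate = TRUE)
  else
    list(snr = m / s, mean = m, sd = s, n_pixels = length(vals),
         degenerate = FALSE)
}

#' b-value dependence of the ADC estimate
#'
#' For every pair of b-values, computes the two-point ADC from the ROI-mean
#' decoded signals and compares it to the all-b log-linear fit of the same
#' ROI-mean signals: \eqn{Dep_b = 100 |ADC_{pair} - ADC_{all}| / ADC_{all}}.
#' Returns the maximum dependence and the pair attaining it, plus the
#' secondary pairwise-vs-pairwise maximum spread with its most outlying
#' pair (\code{spread_pair}, the pair whose ADC deviates most from the
#' median pairwise estimate). The profile's exact reference is not fixed,
#' so both readings are reported; note that under a noise floor the all-b
#' fit itself absorbs part of the corruption, so the floor-affected
#' high-b pair is identified by \code{spread_pair}, not necessarily by
#' \code{worst_pair}.
#'
#' @param series a [DwiSeries-class] with >= 3 distinct b-values.
#' @param roi a single-circle [RoiSet-class].
#' @return list with \code{max_dep_percent}, \code{worst_pair} (s/mm^2),
#'   \code{adc_all}, a per-pair \code{table}, and
#'   \code{pairwise_spread_percent}.
#' @export
bValueDependence <- function(series, roi) {
  stopifnot(methods::is(series, "DwiSeries"))
  b <- series@bValues
  if (length(unique(b)) < 3)
    stop("b-value dependence requires >= 3 distinct b-values")
  phys <- decodeSignal(series)
  d <- dim(phys)[1:3]
  cl <- roi@circles
  if (nrow(cl) != 1) stop("bValueDependence expects a single circular ROI")
  inp <- circleMembership(d, series@voxelSize, cl$x_mm[1], cl$y_mm[1],
                          cl$diameter_mm[1] / 2)
  sbar <- vapply(seq_along(b), function(k) {
    mean(unlist(lapply(roi@slices, function(sl) phys[, , sl, k][inp])))
  }, numeric(1))
  if (any(sbar <= 0)) stop("non-positive ROI-mean signal")
  ## all-b log-linear fit of the ROI-mean signals
  y <- log(sbar)
  bc <- b - mean(b)
  adcAll <- -sum(bc * y) / sum(bc^2) * 1000
  prs <- utils::combn(seq_along(b), 2)
  tab <- data.frame(b1 = b[prs[1, ]], b2 = b[prs[2, ]])
  tab$adc_pair <- mapply(function(i, j) twoPointAdc(sbar[i], sbar[j], b[i], b[j]),
                         prs[1, ], prs[2, ])
  tab$dep_percent <- 100 * abs(tab$adc_pair - adcAll) / adcAll
  worst <- which.max(tab$dep_percent)
  spread <- 100 * (max(tab$adc_pair) - min(tab$adc_pair)) / adcAll
  outlier <- which.max(abs(tab$adc_pair - stats::median(tab$adc_pair)))
  list(max_dep_percent = tab$dep_percent[worst],
       worst_pair = c(tab$b1[worst], tab$b2[worst]),
       adc_all = adcAll,
       table = tab,
       pairwise_spread_percent = spread,
       spread_pair = c(tab$b1[outlier], tab$b2[outlier]))
}

#' Conformance tolerances of the diffusion profile battery
#'
#' The published 2019-profile tolerance set used by [runQibaBattery()]:
#' |bias| <= 3.600%, RC_ST <= 0.015 um^2/ms, CV_ST <= 0.5%, RC_BS <= 0.065
#' um^2/ms, CV_BS <= 2.2%, R^2 > 0.9 with 0.95 <= slope <= 1.05, CV_P < 2%,
#' SNR(b=0) >= 50, Dep_b < 2%. Supply a modified copy to the battery to
#' explore revised profiles.
#'
#' @return named list of tolerance bounds.
#' @export
qibaTolerances <- function() {
  list(bias_abs = 3.600,
       rc_st = 0.015, cv_st = 0.5,
       rc_bs = 0.065, cv_bs = 2.2,
       r2_min = 0.9, slope_min = 0.95, slope_max = 1.05,
       cv_p = 2,
       snr_min = 50,
       dep_b = 2)
}

## numerical guard so exact-boundary values are not decided by float rounding
.tolEps <- 1e-9

#' Per-vial ROI measurements for one series
#'
#' Fits the ADC map of a series and extracts pooled vial ROI statistics,
#' carrying the series provenance — the measurement unit consumed by the
#' battery and the multi-scanner aggregation.
#'
#' @param series a [DwiSeries-class].
#' @param layout a [PhantomLayout-class].
#' @param bSubset,weighted passed to [fitAdcMap()].
#' @param roiDiameterMm ROI diameter; default 60% of the vial diameter,
#'   emulating automated full-vial analysis ROIs.
#' @param nSlices central slices used.
#' @return data.frame: vial_id, mean_adc, sd_adc, n_pixels, scanner, day,
#'   repetition.
#' @export
measureVialAdc <- function(series, layout, bSubset = NULL, weighted = FALSE,
                           roiDiameterMm = NULL, nSlices = 3) {
  if (is.null(roiDiameterMm))
    roiDiameterMm <- 1.2 * min(layout@vials$radius_mm)
  map <- fitAdcMap(series, bSubset = bSubset, weighted = weighted)
  measureVialAdcFromMap(map, series, layout, roiDiameterMm, nSlices)
}

## vial measurements from an already-fitted map (battery fast path)
measureVialAdcFromMap <- function(map, series, layout, roiDiameterMm,
                                  nSlices) {
  rois <- placeVialRois(layout, map, diameterMm = roiDiameterMm,
                        nSlices = nSlices)
  st <- extractRoiStats(map, rois)
  data.frame(vial_id = layout@vials$vial_id,
             mean_adc = st$mean_adc,
             sd_adc = st$sd_adc,
             n_pixels = st$n_pixels,
             scanner = series@scannerId,
             day = series@day,
             repetition = series@repetition,
             stringsAsFactors = FALSE)
}

batteryRow <- function(test, metric, value, tolerance, passed, note = "") {
  data.frame(test = test, metric = metric, value = value,
             tolerance = tolerance, passed = passed, note = note,
             stringsAsFactors = FALSE)
}

#' Run the diffusion profile conformance battery (tests A-G)
#'
#' From a repetition/day-structured set of phantom series on one scanner,
#' computes: A — percent bias of the central water vial (day 1, repetition
#' 1) against its reference; B — short-term repeatability RC_ST/CV_ST over
#' the day-1 repetitions; C — between-session repeatability RC_BS/CV_BS over
#' the first measurements of consecutive days (reported N/A when day 2 is
#' absent); D — linearity of measured versus reference ADC over all vials
#' (repetition 1); E — within-ROI precision CV_P (repetition 1); F — SNR of
#' the b = 0 image; G — b-value dependence. Each metric is compared against
#' its profile tolerance (see [qibaTolerances()]).
#'
#' @param study list of [DwiSeries-class] objects for one scanner, carrying
#'   day/repetition labels (e.g. from [simulateStudy()]).
#' @param layout a [PhantomLayout-class].
#' @param tolerances tolerance list, default [qibaTolerances()].
#' @param roiDiameterMm battery ROI diameter; default 60% of the vial
#'   diameter (automated analysis ROIs).
#' @param nSlices central slices per ROI.
#' @param biasFrom \code{"first"} (default): test A uses day-1 repetition 1;
#'   \code{"mean"}: average of the day-1 repetitions.
#' @param bSubset optional b-value subset for fitting (two-b protocols).
#' @return data.frame of conformance results, one row per reported metric:
#'   \code{test}, \code{metric}, \code{value}, \code{tolerance},
#'   \code{passed} (NA for N/A entries), \code{note}.
#' @export
runQibaBattery <- function(study, layout, tolerances = qibaTolerances(),
                           roiDiameterMm = NULL, nSlices = 3,
                           biasFrom = c("first", "mean"), bSubset = NULL) {
  biasFrom <- match.arg(biasFrom)
  stopifnot(length(study) >= 1)
  if (is.null(roiDiameterMm))
    roiDiameterMm <- 1.2 * min(layout@vials$radius_mm)
  days <- vapply(study, function(s) s@day, integer(1))
  reps <- vapply(study, function(s) s@repetition, integer(1))
  d1 <- which(days == min(days))
  if (!length(d1)) stop("no day-1 series supplied")
  d1 <- d1[order(reps[d1])]
  if (length(d1) < 2)
    stop("test B requires >= 2 same-day repetitions; got ", length(d1))
  ## per-repetition vial measurements, day 1 (rep 1 map kept for E/F/G)
  map1 <- fitAdcMap(study[[d1[1]]], bSubset = bSubset)
  meas <- c(
    list(measureVialAdcFromMap(map1, study[[d1[1]]], layout, roiDiameterMm,
                               nSlices)),
    lapply(study[d1[-1]], measureVialAdc, layout = layout,
           bSubset = bSubset, roiDiameterMm = roiDiameterMm,
           nSlices = nSlices))
  centerId <- layout@vials$vial_id[layout@vials$ring == "center"]
  v1 <- vapply(meas, function(m) m$mean_adc[m$vial_id == centerId], numeric(1))
  ref1 <- referenceAdc(layout, centerId)
  eps <- .tolEps
  out <- list()

  ## A: accuracy
  aVal <- if (biasFrom == "first") v1[1] else mean(v1)
  biasA <- percentBias(aVal, ref1)
  out$A <- batteryRow("A", "bias_percent", biasA,
                      sprintf("|bias| <= %.3f", tolerances$bias_abs),
                      abs(biasA) <= tolerances$bias_abs + eps)

  ## B: short-term repeatability over day-1 repetitions
  rep1 <- repeatability(v1)
  out$B1 <- batteryRow("B", "RC_ST_um2ms", rep1$RC,
                       sprintf("RC_ST <= %.3f", tolerances$rc_st),
                       rep1$RC <= tolerances$rc_st + eps)
  out$B2 <- batteryRow("B", "CV_ST_percent", rep1$CV,
                       sprintf("CV_ST <= %.1f", tolerances$cv_st),
                       rep1$CV <= tolerances$cv_st + eps)

  ## C: between-session repeatability over day firsts
  otherDays <- sort(unique(days[days > min(days)]))
  if (length(otherDays)) {
    firsts <- c(v1[1], vapply(otherDays, function(dd) {
      idx <- which(days == dd)
      idx <- idx[which.min(reps[idx])]
      m <- measureVialAdc(study[[idx]], layout, bSubset = bSubset,
                          roiDiameterMm = roiDiameterMm, nSlices = nSlices)
      m$mean_adc[m$vial_id == centerId]
    }, numeric(1)))
    repC <- repeatability(firsts)
    out$C1 <- batteryRow("C", "RC_BS_um2ms", repC$RC,
                         sprintf("RC_BS <= %.3f", tolerances$rc_bs),
                         repC$RC <= tolerances$rc_bs + eps)
    out$C2 <- batteryRow("C", "CV_BS_percent", repC$CV,
                         sprintf("CV_BS <= %.1f", tolerances$cv_bs),
                         repC$CV <= tolerances$cv_bs + eps)
  } else {
    out$C1 <- batteryRow("C", "RC_BS_um2ms", NA_real_,
                         sprintf("RC_BS <= %.3f", tolerances$rc_bs), NA,
                         note = "N/A: no second day available")
    out$C2 <- batteryRow("C", "CV_BS_percent", NA_real_,
                         sprintf("CV_BS <= %.1f", tolerances$cv_bs), NA,
                         note = "N/A: no second day available")
  }

  ## D: linearity over all vials, repetition 1
  m1 <- meas[[1]]
  lin <- linearity(m1$mean_adc, referenceAdc(layout, m1$vial_id))
  out$D1 <- batteryRow("D", "r_squared", lin$r_squared,
                       sprintf("R2 > %.1f", tolerances$r2_min),
                       lin$r_squared > tolerances$r2_min - eps)
  out$D2 <- batteryRow("D", "slope", lin$slope,
                       sprintf("%.2f <= slope <= %.2f", tolerances$slope_min,
                               tolerances$slope_max),
                       lin$slope >= tolerances$slope_min - eps &&
                         lin$slope <= tolerances$slope_max + eps)

  ## E, F, G on day-1 repetition 1
  s1 <- study[[d1[1]]]
  center <- layout@vials[layout@vials$ring == "center", ]
  roi1 <- circleRoi(center$x_mm, center$y_mm, roiDiameterMm,
                    centralSlices(dim(map1)[3], nSlices), "vial_center")
  cvp <- precisionCv(map1, roi1)
  out$E <- batteryRow("E", "CV_P_percent", cvp,
                      sprintf("CV_P < %.0f", tolerances$cv_p),
                      cvp < tolerances$cv_p + eps)

  if (any(s1@bValues == 0)) {
    sn <- snrB0(s1, roi1)
    out$F <- batteryRow("F", "SNR_b0", sn$snr,
                        sprintf("SNR >= %.0f", tolerances$snr_min),
                        sn$snr >= tolerances$snr_min - eps,
                        note = if (sn$degenerate) "degenerate: zero SD" else "")
  } else {
    out$F <- batteryRow("F", "SNR_b0", NA_real_,
                        sprintf("SNR >= %.0f", tolerances$snr_min), NA,
                        note = "N/A: no b = 0 volume")
  }

  if (length(unique(s1@bValues)) >= 3) {
    dep <- bValueDependence(s1, roi1)
    out$G <- batteryRow("G", "max_dep_b_percent", dep$max_dep_percent,
                        sprintf("Dep_b < %.0f", tolerances$dep_b),
                        dep$max_dep_percent < tolerances$dep_b + eps,
                        note = sprintf("worst pair: %g, %g s/mm2",
                                       dep$worst_pair[1], dep$worst_pair[2]))
  } else {
    out$G <- batteryRow("G", "max_dep_b_percent", NA_real_,
                        sprintf("Dep_b < %.0f", tolerances$dep_b), NA,
                        note = "N/A: fewer than 3 b-values")
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
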