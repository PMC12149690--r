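#' Grand-row aggregation over vials
#'
#' The multi-study report's "average over all vials" row: the unweighted
#' mean of the per-vial inter-scanner bias values and of the per-vial
#' inter-scanner CV values.
#'
#' @param biasPercent per-vial inter-scanner mean bias values, %.
#' @param cvPercentValues per-vial inter-scanner CV values, %.
#' @return named numeric: \code{bias_percent}, \code{cv_percent}.
#' @export
grandRowSummary <- function(biasPercent, cvPercentValues) {
  c(bias_percent = mean(as.numeric(biasPercent)),
    cv_percent = mean(as.numeric(cvPercentValues)))
}

#' Multi-scanner per-vial bias and reproducibility summary
#'
#' Aggregates day-1 vial measurements from several scanners the way a
#' multi-study phantom report does: first the intra-scanner average ADC per
#' vial (mean over the same-day repetitions) and its percent bias against
#' the vial reference; then, per vial, the inter-scanner mean bias (mean of
#' the per-scanner biases) and the inter-scanner CV (coefficient of
#' variation of the per-scanner day-1 vial ADC means); finally the
#' unweighted grand row over vials.
#'
#' @param measurements data.frame with columns \code{scanner},
#'   \code{vial_id}, \code{repetition}, \code{mean_adc} — day-1 vial ROI
#'   means, e.g. rows of [measureVialAdc()] over the repetitions of each
#'   scanner. All scanners must cover the same vial set.
#' @param layout a [PhantomLayout-class] supplying reference ADC values.
#' @return list with \code{per_scanner} (scanner, vial_id, mean_adc,
#'   bias_percent), \code{per_vial} (vial_id, reference_adc, mean_adc,
#'   bias_percent, cv_percent), and \code{grand} (named numeric from
#'   [grandRowSummary()]).
#' @export
multiStudySummary <- function(measurements, layout) {
  need <- c("scanner", "vial_id", "repetition", "mean_adc")
  stopifnot(all(need %in% names(measurements)),
            methods::is(layout, "PhantomLayout"))
  scanners <- sort(unique(measurements$scanner))
  if (length(scanners) < 2)
    stop("multi-study summary requires >= 2 scanners")
  vialSets <- lapply(scanners, function(sc)
    sort(unique(measurements$vial_id[measurements$scanner == sc])))
  if (length(unique(vapply(vialSets, paste, character(1), collapse = ","))) != 1)
    stop("scanners cover different vial sets")
  vialIds <- vialSets[[1]]

  perScanner <- do.call(rbind, lapply(scanners, function(sc) {
    do.call(rbind, lapply(vialIds, function(v) {
      x <- measurements$mean_adc[measurements$scanner == sc &
                                   measurements$vial_id == v]
      m <- mean(x)
      data.frame(scanner = sc, vial_id = v, mean_adc = m,
                 bias_percent = percentBias(m, referenceAdc(layout, v)),
                 n_repetitions = length(x), stringsAsFactors = FALSE)
    }))
  }))

  perVial <- do.call(rbind, lapply(vialIds, function(v) {
    rows <- perScanner[perScanner$vial_id == v, ]
    data.frame(vial_id = v,
               reference_adc = referenceAdc(layout, v),
               mean_adc = mean(rows$mean_adc),
               bias_percent = mean(rows$bias_percent),
               cv_percent = cvPercent(rows$mean_adc),
               stringsAsFactors = FALSE)
  }))

  list(per_scanner = perScanner,
       per_vial = perVial,
       grand = grandRowSummary(perVial$bias_percent, perVial$cv_percent))
}

#' Per-organ repeatability and reproducibility summary
#'
#' For organ-level measurements keyed by scanner, day and organ: the
#' between-session CV (CV_BS) per scanner from the two day means (reported
#' NA when a second contained day is absent), and the inter-scanner day-1
#' mean, SD and CV across scanners. Organs not fully contained in the field
#' of view (\code{contained = FALSE}) are excluded.
#'
#' @param measurements data.frame with columns \code{scanner}, \code{day},
#'   \code{organ}, \code{mean_adc}, \code{contained} (e.g. built from
#'   [organMaskStats()] rows).
#' @return list with \code{per_scanner} (organ, scanner, n_days, mean_adc,
#'   cv_bs_percent) and \code{inter_scanner} (organ, n_scanners, mean_adc,
#'   sd_adc, cv_percent).
#' @export
organLevelSummary <- function(measurements) {
  need <- c("scanner", "day", "organ", "mean_adc", "contained")
  stopifnot(all(need %in% names(measurements)))
  m <- measurements[measurements$contained, , drop = FALSE]
  organs <- sort(unique(measurements$organ))
  scanners <- sort(unique(measurements$scanner))

  perScanner <- do.call(rbind, lapply(organs, function(og) {
    do.call(rbind, lapply(scanners, function(sc) {
      rows <- m[m$organ == og & m$scanner == sc, ]
      dayMeans <- vapply(sort(unique(rows$day)),
                         function(dd) mean(rows$mean_adc[rows$day == dd]),
                         numeric(1))
      data.frame(organ = og, scanner = sc, n_days = length(dayMeans),
                 mean_adc = if (length(dayMeans)) mean(dayMeans) else NA_real_,
                 cv_bs_percent = if (length(dayMeans) >= 2)
                   cvPercent(dayMeans) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))

  interScanner <- do.call(rbind, lapply(organs, function(og) {
    rows <- m[m$organ == og & m$day == 1, ]
    day1 <- vapply(sort(unique(rows$scanner)),
                   function(sc) mean(rows$mean_adc[rows$scanner == sc]),
                   numeric(1))
    data.frame(organ = og, n_scanners = length(day1),
               mean_adc = if (length(day1)) mean(day1) else NA_real_,
               sd_adc = if (length(day1) >= 2) stats::sd(day1) else NA_real_,
               cv_percent = if (length(day1) >= 2) cvPercent(day1) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  list(per_scanner = perScanner, inter_scanner = interScanner)
}
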