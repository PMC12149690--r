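#' Decode stored values to physical signal
#'
#' Scanner exports carry stored (encoded) pixel values; the physical signal
#' is \code{stored * slope + intercept}. The package applies this mapping
#' exactly once, at fit time.
#'
#' @param stored numeric vector/array of stored values.
#' @param slope,intercept rescale parameters; \code{slope} must be non-zero.
#' @return physical values, same shape as \code{stored}.
#' @seealso [encodeRescale()] for the inverse used by the writers.
#' @export
applyRescale <- function(stored, slope, intercept) {
  if (slope == 0) stop("rescale slope must be non-zero")
  stored * slope + intercept
}

#' Encode physical signal to stored values
#'
#' Inverse of [applyRescale()]: \code{stored = (physical - intercept) / slope}.
#'
#' @param physical numeric vector/array.
#' @param slope,intercept rescale parameters; \code{slope} must be non-zero.
#' @return stored values, same shape as \code{physical}.
#' @export
encodeRescale <- function(physical, slope, intercept) {
  if (slope == 0) stop("rescale slope must be non-zero")
  (physical - intercept) / slope
}

#' Two-point ADC estimate from a pair of signals
#'
#' Closed form of the mono-exponential model for exactly two b-values:
#' \eqn{ADC = \ln(S_1/S_2) / (b_2 - b_1)}, returned in um^2/ms.
#'
#' @param s1,s2 physical signals at \code{b1} and \code{b2} (must be > 0).
#' @param b1,b2 b-values, s/mm^2 (must differ).
#' @return ADC in um^2/ms.
#' @examples
#' twoPointAdc(860.7, 606.5, 150, 500)  # ~1.000
#' @export
twoPointAdc <- function(s1, s2, b1, b2) {
  if (b1 == b2) stop("b-values must differ")
  if (any(s1 <= 0) || any(s2 <= 0))
    stop("signals must be positive for a two-point ADC")
  log(s1 / s2) / (b2 - b1) * 1000  # mm2/s -> um2/ms
}

#' Fit an ADC map from a diffusion series
#'
#' Per voxel, decodes stored values to physical signal and fits
#' \eqn{\ln S = \ln S_0 - b \cdot ADC} by least squares over the selected
#' b-values. The default is ordinary (uniform-weight) least squares on
#' log-signal, the conventional reading of the mono-exponential model; a
#' signal-weighted variant (weights proportional to the squared signal,
#' which approximates maximum likelihood for Gaussian noise on the linear
#' scale) is available behind \code{weighted = TRUE}. With exactly two
#' b-values the fit reduces analytically to the [twoPointAdc()] log-ratio.
#'
#' Voxels with any selected signal at or below the floor are masked invalid;
#' negative fitted values are retained (not clamped) so that noise
#' statistics remain unbiased — see [clampNegativeAdc()] for a report-time
#' clamp.
#'
#' @param series a [DwiSeries-class].
#' @param bSubset optional b-values to fit over (default: all in the
#'   series). Standardized phantom protocols fit all four b-values; the
#'   anatomy-specific two-b convention is obtained with
#'   \code{bSubset = c(150, 500)}. Values not present in the series raise an
#'   error, as does a subset with fewer than 2 distinct b-values.
#' @param method \code{"loglinear_lsq"} (any number of b-values) or
#'   \code{"two_point"} (exactly two).
#' @param weighted logical; use signal^2 weights in the log-domain fit.
#' @param floor signal floor for the validity mask; default
#'   \code{1e-6 * max(physical signal)}.
#' @return an [AdcMap-class] in um^2/ms.
#' @examples
#' lay <- builtinLayout()
#' cfg <- simConfig(noiseModel = "none", matrixSize = c(96L, 96L, 5L),
#'                  voxelSize = c(2, 2, 4))
#' map <- fitAdcMap(simulatePhantomSeries(lay, cfg))
#' @export
fitAdcMap <- function(series, bSubset = NULL,
                      method = c("loglinear_lsq", "two_point"),
                      weighted = FALSE, floor = NULL) {
  stopifnot(methods::is(series, "DwiSeries"))
  method <- match.arg(method)
  b <- series@bValues
  if (is.null(bSubset)) bSubset <- b
  if (!all(bSubset %in% b))
    stop("b_subset values not present in series: ",
         paste(setdiff(bSubset, b), collapse = ", "))
  bSubset <- sort(unique(bSubset))
  if (length(bSubset) < 2)
    stop("at least 2 distinct b-values are required to fit an ADC")
  if (method == "two_point" && length(bSubset) != 2)
    stop("two_point method requires exactly 2 b-values")
  sel <- match(bSubset, b)

  phys <- applyRescale(series@signal, series@rescaleSlope,
                       series@rescaleIntercept)
  d <- dim(phys)
  if (is.null(floor)) floor <- 1e-6 * max(phys)
  nvox <- prod(d[1:3])
  M <- matrix(phys, nvox, d[4])[, sel, drop = FALSE]
  valid <- rowSums(M <= floor | !is.finite(M)) == 0L
  Y <- log(pmax(M, .Machine$double.xmin))  # masked rows never reported

  if (method == "two_point") {
    adc_mm2s <- (Y[, 1] - Y[, 2]) / (bSubset[2] - bSubset[1])
  } else if (!weighted) {
    bc <- bSubset - mean(bSubset)
    adc_mm2s <- -as.vector(Y %*% (bc / sum(bc^2)))
  } else {
    W <- M^2
    bm <- matrix(bSubset, nvox, length(bSubset), byrow = TRUE)
    sw <- rowSums(W)
    xbar <- rowSums(W * bm) / sw
    bcent <- bm - xbar
    adc_mm2s <- -rowSums(W * bcent * Y) / rowSums(W * bcent^2)
  }
  adc <- array(adc_mm2s * 1000, dim = d[1:3])  # mm2/s -> um2/ms
  adc[!valid] <- NA_real_
  methods::new("AdcMap",
               adc = adc,
               validMask = array(valid, dim = d[1:3]),
               bValuesUsed = bSubset,
               fitMethod = method,
               units = "um2/ms",
               voxelSize = series@voxelSize,
               provenance = list(scanner_id = series@scannerId,
                                 day = series@day,
                                 repetition = series@repetition,
                                 sequence_name = series@sequenceName,
                                 signal_floor = floor,
                                 weighted = weighted))
}

#' Clamp negative ADC values in a map (report-time option)
#'
#' @param map an [AdcMap-class].
#' @param at value to clamp to (default 0).
#' @return the map with negative fitted values replaced.
#' @export
clampNegativeAdc <- function(map, at = 0) {
  stopifnot(methods::is(map, "AdcMap"))
  a <- map@adc
  a[map@validMask & a < 0] <- at
  map@adc <- a
  map
}

#' Convert an ADC map between um^2/ms and um^2/s
#'
#' @param map an [AdcMap-class].
#' @param units target units, \code{"um2/ms"} or \code{"um2/s"}.
#' @return the converted map.
#' @export
convertAdcUnits <- function(map, units = c("um2/ms", "um2/s")) {
  units <- match.arg(units)
  if (identical(map@units, units)) return(map)
  fac <- if (units == "um2/s") 1000 else 1 / 1000
  map@adc <- map@adc * fac
  map@units <- units
  map
}

#' Compare two ADC maps within an ROI
#'
#' Computes the signed percent difference of ROI means,
#' \eqn{100 (\bar{A} - \bar{B}) / \bar{B}}, after harmonizing units
#' (um^2/s maps are converted to um^2/ms before comparison). Used to compare
#' scanner-generated (inline) maps against maps refitted from exported
#' b-value images (offline), typically with a ~1 cm ROI on the central three
#' slices.
#'
#' @param mapA,mapB [AdcMap-class] objects on the same grid.
#' @param roi a single-ROI [RoiSet-class] (one circle or one mask).
#' @return list with \code{percent_diff}, \code{mean_a}, \code{mean_b}, and
#'   per-slice means of both maps.
#' @export
compareAdcMaps <- function(mapA, mapB, roi) {
  stopifnot(methods::is(mapA, "AdcMap"), methods::is(mapB, "AdcMap"))
  if (!identical(dim(mapA@adc), dim(mapB@adc)))
    stop("ADC maps are on different grids")
  mapA <- convertAdcUnits(mapA, "um2/ms")
  mapB <- convertAdcUnits(mapB, "um2/ms")
  sa <- extractRoiStats(mapA, roi)
  sb <- extractRoiStats(mapB, roi)
  if (!sa$contained[1] || !sb$contained[1])
    stop("ROI has no valid voxels in one of the maps")
  list(percent_diff = 100 * (sa$mean_adc[1] - sb$mean_adc[1]) / sb$mean_adc[1],
       mean_a = sa$mean_adc[1],
       mean_b = sb$mean_adc[1],
       per_slice_means_a = sa$per_slice_means[[1]],
       per_slice_means_b = sb$per_slice_means[[1]])
}
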