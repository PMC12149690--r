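#' PhantomLayout: geometry and reference diffusivities of the 13-vial phantom
#'
#' Describes a CaliberMRI/NIST-style isotropic diffusion phantom: a central
#' water vial surrounded by an inner and an outer ring of vials filled with
#' aqueous polyvinylpyrrolidone (PVP) solutions of increasing concentration,
#' whose reference ADC values at 0 degrees C decrease with PVP concentration.
#'
#' The \code{vials} slot is a data.frame with one row per vial and columns
#' \code{vial_id}, \code{ring} (\code{"center"}, \code{"inner"},
#' \code{"outer"}), \code{pvp_percent} (mass fraction, informational),
#' \code{reference_adc} (um^2/ms at 0 C), \code{x_mm}, \code{y_mm} (in-plane
#' position relative to the phantom axis), \code{radius_mm}, and
#' \code{s0_scale} (relative b = 0 signal of the fill, emulating
#' T2-weighting; informational for simulation).
#'
#' @slot vials data.frame as described above.
#' @slot phantomRadius numeric, phantom radius in mm.
#' @slot slabThickness numeric, extent of the vials along the slice axis, mm.
#' @slot temperatureC numeric, fill temperature (0 for ice-water baths).
#' @slot serialNumber character; reference values are serial-number specific.
#'
#' @seealso [builtinLayout()], [referenceAdc()], [readPhantomLayout()]
#' @export
setClass("PhantomLayout",
  representation(
    vials = "data.frame",
    phantomRadius = "numeric",
    slabThickness = "numeric",
    temperatureC = "numeric",
    serialNumber = "character"
  )
)

setValidity("PhantomLayout", function(object) {
  v <- object@vials
  msg <- character()
  need <- c("vial_id", "ring", "pvp_percent", "reference_adc",
            "x_mm", "y_mm", "radius_mm", "s0_scale")
  if (!all(need %in% names(v)))
    return(paste("vials must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(v$vial_id))
    msg <- c(msg, "vial_id values must be unique")
  if (sum(v$ring == "center") != 1L)
    msg <- c(msg, "exactly one vial must have ring = 'center'")
  if (!all(v$ring %in% c("center", "inner", "outer")))
    msg <- c(msg, "ring must be one of 'center', 'inner', 'outer'")
  if (any(v$reference_adc <= 0))
    msg <- c(msg, "reference_adc must be positive")
  if (any(v$radius_mm <= 0))
    msg <- c(msg, "radius_mm must be positive")
  ## reference ADC strictly decreases with increasing PVP concentration
  o <- order(v$pvp_percent)
  pv <- v$pvp_percent[o]; ad <- v$reference_adc[o]
  lev_p <- unique(pv)
  lev_a <- vapply(lev_p, function(p) unique(ad[pv == p])[1], numeric(1))
  for (p in lev_p) {
    if (length(unique(ad[pv == p])) != 1L)
      msg <- c(msg, "vials sharing a PVP concentration must share reference_adc")
  }
  if (any(diff(lev_a) >= 0))
    msg <- c(msg, "reference_adc must strictly decrease with pvp_percent")
  ## no two vial footprints overlap in-plane
  n <- nrow(v)
  if (n > 1) {
    d <- as.matrix(stats::dist(cbind(v$x_mm, v$y_mm)))
    rsum <- outer(v$radius_mm, v$radius_mm, "+")
    diag(d) <- Inf
    if (any(d < rsum))
      msg <- c(msg, "vial footprints overlap in-plane")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' SimulationConfig: parameters of the synthetic diffusion acquisition
#'
#' Holds the acquisition and noise parameters used by the synthetic series
#' generator: b-values, baseline signal, target SNR at b = 0, the noise model,
#' per-scanner multiplicative ADC bias, per-day session drift, geometry, the
#' rescale (stored-value) encoding, and the master seed.
#'
#' @slot bValues numeric, b-values in s/mm^2 (non-negative, >= 2 distinct).
#' @slot s0 numeric, baseline (b = 0) signal of the central water vial,
#'   arbitrary units.
#' @slot snrB0 numeric, target SNR (mean/SD in a uniform water region) at
#'   b = 0; the Gaussian channel SD is calibrated as \code{s0 / snrB0}.
#' @slot noiseModel character, one of \code{"none"}, \code{"gaussian"},
#'   \code{"rician"}.
#' @slot scannerBiasPercent named numeric, multiplicative ADC offset (%) per
#'   scanner identifier.
#' @slot sessionDriftPercent numeric, per-day multiplicative ADC offset (%)
#'   applied as \code{(1 + drift/100)^(day - 1)}.
#' @slot voxelSize numeric(3), voxel edge lengths in mm (row, col, slice).
#' @slot matrixSize integer(3), image dimensions (rows, cols, slices).
#' @slot seed integer master seed; identical (config, seed) pairs reproduce
#'   identical series.
#' @slot rescaleSlope,rescaleIntercept numeric, stored-value encoding
#'   (physical = stored * slope + intercept).
#' @slot shadingPercent numeric, amplitude (%) of an optional low-order
#'   in-plane multiplicative shading field (0 disables; non-physical, for
#'   robustness experiments only).
#'
#' @seealso [simConfig()], [simulatePhantomSeries()], [simulateStudy()]
#' @export
setClass("SimulationConfig",
  representation(
    bValues = "numeric",
    s0 = "numeric",
    snrB0 = "numeric",
    noiseModel = "character",
    scannerBiasPercent = "numeric",
    sessionDriftPercent = "numeric",
    voxelSize = "numeric",
    matrixSize = "integer",
    seed = "integer",
    rescaleSlope = "numeric",
    rescaleIntercept = "numeric",
    shadingPercent = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  b <- object@bValues
  if (length(unique(b)) < 2 || any(b < 0))
    msg <- c(msg, "bValues must be non-negative with at least 2 distinct values")
  if (object@s0 <= 0) msg <- c(msg, "s0 must be positive")
  if (!object@noiseModel %in% c("none", "gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'none', 'gaussian' or 'rician'")
  if (object@noiseModel != "none" && object@snrB0 <= 0)
    msg <- c(msg, "snrB0 must be positive when noise is enabled")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (length(object@matrixSize) != 3 || any(object@matrixSize < 1))
    msg <- c(msg, "matrixSize must be 3 positive integers")
  if (object@rescaleSlope == 0) msg <- c(msg, "rescaleSlope must be non-zero")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' DwiSeries: a 4-D diffusion-weighted image series
#'
#' One image volume per b-value, in stored (encoded) values, together with
#' the rescale mapping back to physical signal, voxel geometry and
#' acquisition provenance (scanner, day, repetition, sequence).
#'
#' The signal array is indexed \code{[row, col, slice, b]}; volumes are kept
#' sorted by ascending b-value. Physical signal is
#' \code{stored * rescaleSlope + rescaleIntercept} (see [decodeSignal()]).
#'
#' @slot signal 4-D numeric array of stored values.
#' @slot bValues numeric, one b-value (s/mm^2) per volume, ascending.
#' @slot rescaleSlope,rescaleIntercept numeric scalars.
#' @slot voxelSize numeric(3), mm.
#' @slot scannerId character scanner label.
#' @slot day,repetition integer session labels.
#' @slot sequenceName character, e.g. \code{"qiba_epi"}.
#'
#' @seealso [simulatePhantomSeries()], [fitAdcMap()], [readDwiSeries()]
#' @export
setClass("DwiSeries",
  representation(
    signal = "array",
    bValues = "numeric",
    rescaleSlope = "numeric",
    rescaleIntercept = "numeric",
    voxelSize = "numeric",
    scannerId = "character",
    day = "integer",
    repetition = "integer",
    sequenceName = "character"
  )
)

setValidity("DwiSeries", function(object) {
  msg <- character()
  d <- dim(object@signal)
  if (length(d) != 4)
    return("signal must be a 4-D array [row, col, slice, b]")
  if (d[4] != length(object@bValues))
    msg <- c(msg, "one volume per b-value required")
  if (is.unsorted(object@bValues))
    msg <- c(msg, "volumes must be ordered by ascending b-value")
  if (any(object@bValues < 0)) msg <- c(msg, "b-values must be non-negative")
  if (object@rescaleSlope == 0) msg <- c(msg, "rescaleSlope must be non-zero")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be 3 positive lengths (mm)")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' AdcMap: a fitted apparent diffusion coefficient volume
#'
#' Per-voxel ADC estimates in um^2/ms (1 um^2/ms = 1e-3 mm^2/s) with a
#' validity mask (fit succeeded; all signals above the floor), the b-values
#' used, the fit method, and provenance copied from the source series.
#'
#' @slot adc 3-D numeric array, um^2/ms (unless \code{units} says otherwise).
#' @slot validMask 3-D logical array, same dimensions as \code{adc}.
#' @slot bValuesUsed numeric, subset of the source b-values (length >= 2).
#' @slot fitMethod character, \code{"loglinear_lsq"} or \code{"two_point"}.
#' @slot units character, \code{"um2/ms"} or \code{"um2/s"}; public maps are
#'   produced in um^2/ms, the alternative exists for comparing against
#'   externally generated maps.
#' @slot voxelSize numeric(3), mm.
#' @slot provenance named list (scanner_id, day, repetition, sequence_name,
#'   signal_floor, weighted).
#'
#' @seealso [fitAdcMap()], [compareAdcMaps()], [writeAdcMap()]
#' @export
setClass("AdcMap",
  representation(
    adc = "array",
    validMask = "array",
    bValuesUsed = "numeric",
    fitMethod = "character",
    units = "character",
    voxelSize = "numeric",
    provenance = "list"
  )
)

setValidity("AdcMap", function(object) {
  msg <- character()
  if (length(dim(object@adc)) != 3) return("adc must be a 3-D array")
  if (!identical(dim(object@adc), dim(object@validMask)))
    msg <- c(msg, "validMask must match adc dimensions")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (any(!is.finite(object@adc[object@validMask])))
    msg <- c(msg, "adc must be finite wherever validMask is TRUE")
  if (length(object@bValuesUsed) < 2)
    msg <- c(msg, "at least 2 b-values are needed for a fit")
  if (!object@fitMethod %in% c("loglinear_lsq", "two_point"))
    msg <- c(msg, "fitMethod must be 'loglinear_lsq' or 'two_point'")
  if (!object@units %in% c("um2/ms", "um2/s"))
    msg <- c(msg, "units must be 'um2/ms' or 'um2/s'")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' RoiSet: circular vial ROIs and/or 3-D mask ROIs
#'
#' Circular regions are defined in physical in-plane coordinates (mm from the
#' phantom/volume axis) and replicated on a set of slices; mask regions are
#' full 3-D logical arrays. Pixel membership of a circle is decided by the
#' pixel-center-inside-circle rule in 0-based voxel coordinates, with the
#' nearest pixel to the center always included so degenerate (sub-pixel)
#' circles still measure one pixel.
#'
#' @slot circles data.frame with columns \code{label}, \code{x_mm},
#'   \code{y_mm}, \code{diameter_mm}.
#' @slot slices integer vector of 1-based slice indices the circles cover.
#' @slot masks named list of 3-D logical arrays.
#'
#' @seealso [placeVialRois()], [extractRoiStats()]
#' @export
setClass("RoiSet",
  representation(
    circles = "data.frame",
    slices = "integer",
    masks = "list"
  )
)

setValidity("RoiSet", function(object) {
  msg <- character()
  cl <- object@circles
  if (nrow(cl)) {
    if (!all(c("label", "x_mm", "y_mm", "diameter_mm") %in% names(cl)))
      return("circles needs columns label, x_mm, y_mm, diameter_mm")
    if (any(cl$diameter_mm <= 0)) msg <- c(msg, "circle diameters must be > 0")
  }
  labs <- c(as.character(cl$label), names(object@masks))
  if (anyDuplicated(labs)) msg <- c(msg, "ROI labels must be unique")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "PhantomLayout", function(object) {
  v <- object@vials
  cat("PhantomLayout (serial ", object@serialNumber, ")\n", sep = "")
  cat("  ", nrow(v), " vials (",
      sum(v$ring == "center"), " center / ",
      sum(v$ring == "inner"), " inner / ",
      sum(v$ring == "outer"), " outer)\n", sep = "")
  cat("  reference ADC range: ",
      format(min(v$reference_adc)), " - ", format(max(v$reference_adc)),
      " um2/ms at ", object@temperatureC, " C\n", sep = "")
  cat("  phantom radius ", object@phantomRadius, " mm, slab ",
      object@slabThickness, " mm\n", sep = "")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig\n")
  cat("  b-values (s/mm2):", paste(object@bValues, collapse = ", "), "\n")
  cat("  matrix ", paste(object@matrixSize, collapse = " x "),
      ", voxel ", paste(object@voxelSize, collapse = " x "), " mm\n", sep = "")
  cat("  noise:", object@noiseModel,
      if (object@noiseModel != "none") paste0("(SNR at b=0: ", object@snrB0, ")"),
      "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "DwiSeries", function(object) {
  d <- dim(object@signal)
  cat("DwiSeries [", object@sequenceName, "] scanner ", object@scannerId,
      ", day ", object@day, ", repetition ", object@repetition, "\n", sep = "")
  cat("  ", d[1], " x ", d[2], " x ", d[3], " voxels, ", d[4],
      " b-values: ", paste(object@bValues, collapse = ", "), " s/mm2\n",
      sep = "")
  cat("  rescale: slope ", object@rescaleSlope, ", intercept ",
      object@rescaleIntercept, "\n", sep = "")
})

setMethod("show", "AdcMap", function(object) {
  d <- dim(object@adc)
  cat("AdcMap (", object@fitMethod, ", b = ",
      paste(object@bValuesUsed, collapse = ", "), ")\n", sep = "")
  cat("  ", d[1], " x ", d[2], " x ", d[3], " voxels, units ", object@units,
      "; ", sum(object@validMask), " valid voxels\n", sep = "")
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet: ", nrow(object@circles), " circular ROIs on slices ",
      paste(object@slices, collapse = ", "), "; ", length(object@masks),
      " mask ROIs\n", sep = "")
})

## ---- simple accessors -------------------------------------------------

#' @rdname dwiQA-generics
#' @export
setMethod("vials", "PhantomLayout", function(object) object@vials)

#' @rdname dwiQA-generics
#' @export
setMethod("nVials", "PhantomLayout", function(object) nrow(object@vials))

#' @rdname dwiQA-generics
#' @export
setMethod("bValues", "DwiSeries", function(object) object@bValues)

#' @rdname dwiQA-generics
#' @export
setMethod("bValues", "AdcMap", function(object) object@bValuesUsed)

#' @rdname dwiQA-generics
#' @export
setMethod("voxelSize", "DwiSeries", function(object) object@voxelSize)

#' @rdname dwiQA-generics
#' @export
setMethod("voxelSize", "AdcMap", function(object) object@voxelSize)

#' @rdname dwiQA-generics
#' @export
setMethod("adcValues", "AdcMap", function(object) object@adc)

#' @rdname dwiQA-generics
#' @export
setMethod("validMask", "AdcMap", function(object) object@validMask)

#' @rdname dwiQA-generics
#' @export
setMethod("provenance", "AdcMap", function(object) object@provenance)

#' @rdname dwiQA-generics
#' @export
setMethod("adcUnits", "AdcMap", function(object) object@units)

#' @rdname dwiQA-generics
#' @export
setMethod("decodeSignal", "DwiSeries", function(object) {
  applyRescale(object@signal, object@rescaleSlope, object@rescaleIntercept)
})

#' @describeIn dwiQA-generics dimensions of the image grid of a series.
#' @export
setMethod("dim", "DwiSeries", function(x) dim(x@signal))

#' @describeIn dwiQA-generics dimensions of the ADC volume.
#' @export
setMethod("dim", "AdcMap", function(x) dim(x@adc))
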