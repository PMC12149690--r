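#' Central slice selection
#'
#' Resolves "the central n slices" of a stack: the lower median slice (for
#' even stack sizes) and its neighbours, matching the convention used for
#' vial ROI placement.
#'
#' @param nTotal total number of slices.
#' @param n number of central slices wanted.
#' @return integer vector of 1-based slice indices.
#' @export
centralSlices <- function(nTotal, n = 3) {
  stopifnot(n >= 1, nTotal >= 1)
  if (n > nTotal) stop("requested ", n, " central slices from ", nTotal)
  c0 <- floor((nTotal + 1) / 2)
  lo <- c0 - floor((n - 1) / 2)
  idx <- seq(lo, lo + n - 1)
  if (idx[1] < 1) idx <- idx - idx[1] + 1
  if (idx[n] > nTotal) idx <- idx - (idx[n] - nTotal)
  idx
}

roiGeometry <- function(x) {
  if (methods::is(x, "AdcMap")) list(dim = dim(x@adc), voxelSize = x@voxelSize)
  else if (methods::is(x, "DwiSeries")) list(dim = dim(x@signal)[1:3],
                                             voxelSize = x@voxelSize)
  else if (is.list(x) && all(c("dim", "voxelSize") %in% names(x))) x
  else stop("geometry must be an AdcMap, DwiSeries, or list(dim, voxelSize)")
}

#' Place circular vial ROIs from phantom geometry
#'
#' One circular ROI per vial, centered at the vial's nominal in-plane
#' position, on the central \code{nSlices} slices of the grid. Pixel
#' membership is decided by the pixel-center-inside-circle rule (0-based
#' voxel indices, physical coordinates at pixel centers); the pixel nearest
#' the center is always included so that sub-pixel ROIs still measure one
#' pixel. The 10 mm default emulates the ~1 cm manual ROIs used for map
#' comparisons; the conformance battery uses wider automated ROIs (see
#' [runQibaBattery()]).
#'
#' @param layout a [PhantomLayout-class].
#' @param geometry an [AdcMap-class], [DwiSeries-class], or
#'   \code{list(dim, voxelSize)} describing the target grid.
#' @param diameterMm ROI diameter in mm.
#' @param nSlices number of central slices.
#' @param centerOffsetMm optional (x, y) offset of the phantom axis relative
#'   to the grid center, mm, for phantoms not positioned at isocenter.
#' @return a [RoiSet-class] with labels \code{"vial_01"} ... An ROI whose
#'   circle extends outside the grid raises an error naming the vial.
#' @export
placeVialRois <- function(layout, geometry, diameterMm = 10, nSlices = 3,
                          centerOffsetMm = c(0, 0)) {
  stopifnot(methods::is(layout, "PhantomLayout"), diameterMm > 0)
  geo <- roiGeometry(geometry)
  v <- layout@vials
  fovx <- geo$dim[2] * geo$voxelSize[2] / 2
  fovy <- geo$dim[1] * geo$voxelSize[1] / 2
  cx <- v$x_mm + centerOffsetMm[1]
  cy <- v$y_mm + centerOffsetMm[2]
  r <- diameterMm / 2
  out <- abs(cx) + r > fovx | abs(cy) + r > fovy
  if (any(out))
    stop("ROI extends outside the grid for vial(s): ",
         paste(v$vial_id[out], collapse = ", "))
  circles <- data.frame(label = sprintf("vial_%02d", v$vial_id),
                        x_mm = cx, y_mm = cy, diameter_mm = diameterMm,
                        stringsAsFactors = FALSE)
  methods::new("RoiSet",
               circles = circles,
               slices = as.integer(centralSlices(geo$dim[3], nSlices)),
               masks = list())
}

#' A single-circle ROI set
#'
#' Convenience constructor for one circular ROI (for map comparisons or SNR
#' measurements).
#'
#' @param x_mm,y_mm in-plane center, mm from the grid axis.
#' @param diameterMm diameter, mm.
#' @param slices integer slice indices.
#' @param label ROI label.
#' @return a [RoiSet-class].
#' @export
circleRoi <- function(x_mm = 0, y_mm = 0, diameterMm = 10, slices = 1L,
                      label = "roi") {
  methods::new("RoiSet",
               circles = data.frame(label = label, x_mm = x_mm, y_mm = y_mm,
                                    diameter_mm = diameterMm,
                                    stringsAsFactors = FALSE),
               slices = as.integer(slices),
               masks = list())
}

## In-plane membership of a circle with the nearest-pixel fallback.
circleMembership <- function(geoDim, voxelSize, cx, cy, radius) {
  inp <- circleFootprint(geoDim, voxelSize, cx, cy, radius)
  if (!any(inp)) {
    g <- gridCoords(geoDim, voxelSize)
    i <- which.min(abs(g$y - cy))
    j <- which.min(abs(g$x - cx))
    inp[i, j] <- TRUE
  }
  inp
}

roiVoxelValues <- function(map, inplane, slices) {
  vals <- lapply(slices, function(sl) {
    a <- map@adc[, , sl][inplane]
    v <- map@validMask[, , sl][inplane]
    list(values = a[v], n_invalid = sum(!v))
  })
  names(vals) <- as.character(slices)
  vals
}

summarizeVoxels <- function(label, perSlice) {
  pooled <- unlist(lapply(perSlice, `[[`, "values"), use.names = FALSE)
  n <- length(pooled)
  perSliceMeans <- vapply(perSlice, function(x) {
    if (length(x$values)) mean(x$values) else NA_real_
  }, numeric(1))
  if (n == 0) {
    return(data.frame(label = label, mean_adc = NA_real_, sd_adc = NA_real_,
                      n_pixels = 0L, n_invalid = sum(vapply(perSlice, `[[`,
                        integer(1), "n_invalid")),
                      contained = FALSE,
                      per_slice_means = I(list(perSliceMeans)),
                      stringsAsFactors = FALSE))
  }
  data.frame(label = label,
             mean_adc = mean(pooled),
             sd_adc = if (n > 1) stats::sd(pooled) else 0,
             n_pixels = n,
             n_invalid = sum(vapply(perSlice, `[[`, integer(1), "n_invalid")),
             contained = TRUE,
             per_slice_means = I(list(perSliceMeans)),
             stringsAsFactors = FALSE)
}

#' Extract ROI statistics from an ADC map
#'
#' Mean and SD are computed over the valid voxels pooled across all ROI
#' slices; per-slice means are returned alongside (the pooled mean equals
#' the pixel-count-weighted mean of the per-slice means). Invalid voxels are
#' excluded and counted. An ROI with zero valid voxels yields
#' \code{contained = FALSE} with undefined (NA) statistics rather than an
#' error.
#'
#' @param map an [AdcMap-class].
#' @param roi a [RoiSet-class].
#' @return data.frame with one row per ROI: \code{label}, \code{mean_adc},
#'   \code{sd_adc} (um^2/ms), \code{n_pixels}, \code{n_invalid},
#'   \code{contained}, and a \code{per_slice_means} list column.
#' @export
extractRoiStats <- function(map, roi) {
  stopifnot(methods::is(map, "AdcMap"), methods::is(roi, "RoiSet"))
  d <- dim(map@adc)
  if (length(roi@slices) && any(roi@slices < 1 | roi@slices > d[3]))
    stop("ROI slices outside the map grid")
  rows <- list()
  cl <- roi@circles
  for (i in seq_len(nrow(cl))) {
    inp <- circleMembership(d, map@voxelSize, cl$x_mm[i], cl$y_mm[i],
                            cl$diameter_mm[i] / 2)
    rows[[length(rows) + 1L]] <-
      summarizeVoxels(cl$label[i], roiVoxelValues(map, inp, roi@slices))
  }
  for (lab in names(roi@masks)) {
    rows[[length(rows) + 1L]] <- organMaskStats(map, roi@masks[[lab]], lab)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Organ-mask statistics with the field-of-view containment rule
#'
#' Computes the same statistics as [extractRoiStats()] over a 3-D binary
#' organ mask. \code{contained} is TRUE only if the mask's source did not
#' flag it as truncated against the field of view
#' (\code{attr(mask, "truncated")}, set by [simulateOrganVolume()] or by the
#' mask reader) and the mask holds at least one valid voxel; non-contained
#' organs are excluded from downstream aggregation.
#'
#' @param map an [AdcMap-class].
#' @param mask 3-D logical array on the same grid as \code{map}.
#' @param label organ label.
#' @return one-row data.frame as in [extractRoiStats()].
#' @export
organMaskStats <- function(map, mask, label = "organ") {
  stopifnot(methods::is(map, "AdcMap"))
  if (!identical(dim(mask), dim(map@adc)))
    stop("mask and map are on different grids")
  if (!any(mask)) stop("empty organ mask: ", label)
  truncated <- isTRUE(attr(mask, "truncated"))
  vals <- map@adc[mask & map@validMask]
  nInv <- sum(mask & !map@validMask)
  n <- length(vals)
  data.frame(label = label,
             mean_adc = if (n) mean(vals) else NA_real_,
             sd_adc = if (n > 1) stats::sd(vals) else if (n == 1) 0 else NA_real_,
             n_pixels = n,
             n_invalid = nInv,
             contained = (n > 0) && !truncated,
             per_slice_means = I(list(stats::setNames(numeric(0), character(0)))),
             stringsAsFactors = FALSE)
}
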