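#' Write a diffusion series as NIfTI volumes with a b-value sidecar
#'
#' The canonical interchange dialect of the package: one 3-D NIfTI file per
#' b-value (\code{<prefix>_vol001.nii}, ...), a plain-text sidecar
#' \code{<prefix>.bval} listing one b-value per volume (single line,
#' space-separated), and a flat key-value metadata file
#' \code{<prefix>_meta.cfg} carrying the rescale parameters and provenance
#' labels. Pixel data are the stored (encoded) values; rescale is recorded
#' in the metadata and applied exactly once, by the reader of the fit stage.
#'
#' @param series a [DwiSeries-class].
#' @param prefix path prefix for the output files.
#' @return character vector of files written, invisibly.
#' @seealso [readDwiSeries()]
#' @export
writeDwiSeries <- function(series, prefix) {
  stopifnot(methods::is(series, "DwiSeries"))
  d <- dim(series@signal)
  files <- character(0)
  for (k in seq_len(d[4])) {
    f <- sprintf("%s_vol%03d.nii", prefix, k)
    img <- RNifti::asNifti(series@signal[, , , k],
                           reference = list(pixdim = c(-1, series@voxelSize,
                                                       rep(0, 4))))
    RNifti::writeNifti(img, f, datatype = "double")
    files <- c(files, f)
  }
  bf <- paste0(prefix, ".bval")
  writeLines(paste(series@bValues, collapse = " "), bf)
  mf <- paste0(prefix, "_meta.cfg")
  writeFlatConfig(c(
    rescale_slope = format(series@rescaleSlope, digits = 17),
    rescale_intercept = format(series@rescaleIntercept, digits = 17),
    scanner_id = series@scannerId,
    day = series@day,
    repetition = series@repetition,
    sequence_name = series@sequenceName
  ), mf, header = "dwi series metadata")
  invisible(c(files, bf, mf))
}

#' Read a diffusion series from the NIfTI + sidecar dialect
#'
#' Inverse of [writeDwiSeries()]. Volumes are re-ordered by ascending
#' b-value; a missing sidecar, a volume/b-value count mismatch, inconsistent
#' volume geometry, and missing rescale metadata each raise a distinct,
#' named error. Rescale parameters are stored on the returned object, never
#' silently applied.
#'
#' @param prefix path prefix used when writing.
#' @return a [DwiSeries-class].
#' @export
readDwiSeries <- function(prefix) {
  files <- sort(Sys.glob(sprintf("%s_vol*.nii", prefix)))
  if (!length(files)) stop("no volumes found for prefix: ", prefix)
  bf <- paste0(prefix, ".bval")
  if (!file.exists(bf)) stop("missing b-value sidecar: ", bf)
  b <- scan(bf, what = numeric(), quiet = TRUE)
  if (length(b) != length(files))
    stop("b-value count mismatch: ", length(b), " b-values for ",
         length(files), " volumes")
  mf <- paste0(prefix, "_meta.cfg")
  if (!file.exists(mf)) stop("missing metadata sidecar: ", mf)
  meta <- readFlatConfig(mf)
  for (key in c("rescale_slope", "rescale_intercept"))
    if (!key %in% names(meta)) stop("missing rescale metadata: ", key)

  vols <- lapply(files, RNifti::readNifti)
  dims <- lapply(vols, dim)
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("inconsistent volume geometry across b-values")
  vs <- RNifti::pixdim(vols[[1]])[1:3]
  d3 <- dims[[1]]
  arr <- array(NA_real_, dim = c(d3, length(vols)))
  for (k in seq_along(vols)) arr[, , , k] <- as.array(vols[[k]])
  o <- order(b)
  methods::new("DwiSeries",
               signal = arr[, , , o, drop = FALSE],
               bValues = b[o],
               rescaleSlope = as.numeric(meta[["rescale_slope"]]),
               rescaleIntercept = as.numeric(meta[["rescale_intercept"]]),
               voxelSize = as.numeric(vs),
               scannerId = meta[["scanner_id"]],
               day = as.integer(meta[["day"]]),
               repetition = as.integer(meta[["repetition"]]),
               sequenceName = meta[["sequence_name"]])
}

#' Write an ADC map as NIfTI with a JSON provenance sidecar
#'
#' The map is written in um^2/ms as float data (invalid voxels as NaN), with
#' \code{<path>.json} recording b-values used, fit method, units, signal
#' floor and acquisition provenance.
#'
#' @param map an [AdcMap-class].
#' @param path output NIfTI path (\code{.nii}).
#' @return files written, invisibly.
#' @export
writeAdcMap <- function(map, path) {
  stopifnot(methods::is(map, "AdcMap"))
  a <- map@adc
  a[!map@validMask] <- NaN
  img <- RNifti::asNifti(a, reference = list(pixdim = c(-1, map@voxelSize,
                                                        rep(0, 4))))
  RNifti::writeNifti(img, path, datatype = "float")
  side <- paste0(path, ".json")
  jsonlite::write_json(
    c(list(b_values_used = map@bValuesUsed,
           fit_method = map@fitMethod,
           units = map@units),
      map@provenance),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Read an ADC map written by [writeAdcMap()]
#'
#' @param path NIfTI path.
#' @return an [AdcMap-class]; NaN voxels become invalid-mask entries.
#' @export
readAdcMap <- function(path) {
  img <- RNifti::readNifti(path)
  side <- paste0(path, ".json")
  if (!file.exists(side)) stop("missing provenance sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  a <- array(as.numeric(img), dim = dim(img))
  valid <- is.finite(a)
  a[!valid] <- NA_real_
  methods::new("AdcMap",
               adc = a,
               validMask = valid,
               bValuesUsed = as.numeric(meta$b_values_used),
               fitMethod = meta$fit_method,
               units = meta$units,
               voxelSize = as.numeric(RNifti::pixdim(img)[1:3]),
               provenance = list(scanner_id = meta$scanner_id,
                                 day = as.integer(meta$day),
                                 repetition = as.integer(meta$repetition),
                                 sequence_name = meta$sequence_name,
                                 signal_floor = as.numeric(meta$signal_floor),
                                 weighted = isTRUE(meta$weighted)))
}
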