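## Minimal single-frame DICOM dialect (explicit VR little endian).
##
## Scope: standard diffusion b-value, rescale and geometry tags on
## single-frame MR images, one file per (slice, b-value). Pixel data are
## unsigned 16-bit with a writer-chosen rescale mapping covering the series'
## physical range, so decoded values carry at most half a quantization step
## of error. Vendor multiframe and private dialects are out of scope; the
## reader exposes an extension hook via the `extraTags` argument.

.dcmTxUID <- "1.2.840.10008.1.2.1"          # explicit VR little endian
.dcmSopClass <- "1.2.840.10008.5.1.4.1.1.4" # MR image storage

.dcmPadString <- function(s, pad = " ") {
  r <- charToRaw(as.character(s))
  if (length(r) %% 2 == 1) r <- c(r, charToRaw(pad))
  r
}

.dcmPayload <- function(vr, value) {
  switch(vr,
    US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
    UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
    FD = writeBin(as.double(value), raw(), size = 8, endian = "little"),
    OW = value,
    UI = {
      r <- charToRaw(as.character(value))
      if (length(r) %% 2 == 1) r <- c(r, as.raw(0))
      r
    },
    .dcmPadString(value)  # CS, LO, SH, DS, IS, ...
  )
}

.dcmElement <- function(group, elem, vr, value) {
  payload <- .dcmPayload(vr, value)
  head <- c(writeBin(as.integer(group), raw(), size = 2, endian = "little"),
            writeBin(as.integer(elem), raw(), size = 2, endian = "little"),
            charToRaw(vr))
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, as.raw(c(0, 0)),
      writeBin(length(payload), raw(), size = 4, endian = "little"), payload)
  } else {
    c(head, writeBin(length(payload), raw(), size = 2, endian = "little"),
      payload)
  }
}

#' Write a diffusion series as a minimal single-frame DICOM series
#'
#' One explicit-VR little-endian file per (slice, b-value), carrying the
#' standard diffusion b-value tag (0018,9087), rescale slope/intercept
#' (0028,1052/1053), geometry (PixelSpacing, SliceThickness, SliceLocation)
#' and the provenance labels (scanner as StationName, day as SeriesNumber,
#' repetition as AcquisitionNumber). Pixels are unsigned 16-bit; the writer
#' picks the rescale mapping to cover the decoded physical range, so stored
#' values are requantized (the NIfTI dialect, [writeDwiSeries()], is the
#' lossless one).
#'
#' @param series a [DwiSeries-class].
#' @param dir output directory (created if needed).
#' @return files written, invisibly.
#' @seealso [readDicomSeries()]
#' @export
writeDicomSeries <- function(series, dir) {
  stopifnot(methods::is(series, "DwiSeries"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  phys <- decodeSignal(series)
  lo <- min(phys); hi <- max(phys)
  slope <- max((hi - lo) / 65535, .Machine$double.eps)
  intercept <- lo
  raw16 <- round((phys - intercept) / slope)
  d <- dim(phys)
  g <- gridCoords(d[1:3], series@voxelSize)
  files <- character(0)
  inst <- 0L
  for (k in seq_len(d[4])) for (s in seq_len(d[3])) {
    inst <- inst + 1L
    body <- c(
      .dcmElement(0x0008, 0x0018, "UI",
                  sprintf("1.2.826.0.1.3680043.9.7435.%d", inst)),
      .dcmElement(0x0008, 0x0060, "CS", "MR"),
      .dcmElement(0x0008, 0x1010, "SH", series@scannerId),
      .dcmElement(0x0008, 0x103E, "LO", series@sequenceName),
      .dcmElement(0x0018, 0x0050, "DS", format(series@voxelSize[3])),
      .dcmElement(0x0018, 0x9087, "FD", series@bValues[k]),
      .dcmElement(0x0020, 0x0011, "IS", as.character(series@day)),
      .dcmElement(0x0020, 0x0012, "IS", as.character(series@repetition)),
      .dcmElement(0x0020, 0x0013, "IS", as.character(inst)),
      .dcmElement(0x0020, 0x1041, "DS", format(g$z[s], digits = 10)),
      .dcmElement(0x0028, 0x0002, "US", 1L),
      .dcmElement(0x0028, 0x0004, "CS", "MONOCHROME2"),
      .dcmElement(0x0028, 0x0010, "US", d[1]),
      .dcmElement(0x0028, 0x0011, "US", d[2]),
      .dcmElement(0x0028, 0x0030, "DS",
                  paste(format(series@voxelSize[1]),
                        format(series@voxelSize[2]), sep = "\\")),
      .dcmElement(0x0028, 0x0100, "US", 16L),
      .dcmElement(0x0028, 0x0101, "US", 16L),
      .dcmElement(0x0028, 0x0102, "US", 15L),
      .dcmElement(0x0028, 0x0103, "US", 0L),
      .dcmElement(0x0028, 0x1052, "DS", format(intercept, digits = 16)),
      .dcmElement(0x0028, 0x1053, "DS", format(slope, digits = 16)),
      .dcmElement(0x7FE0, 0x0010, "OW",
                  writeBin(as.integer(t(raw16[, , s, k])), raw(), size = 2,
                           endian = "little"))
    )
    meta <- c(
      .dcmElement(0x0002, 0x0002, "UI", .dcmSopClass),
      .dcmElement(0x0002, 0x0003, "UI",
                  sprintf("1.2.826.0.1.3680043.9.7435.%d", inst)),
      .dcmElement(0x0002, 0x0010, "UI", .dcmTxUID)
    )
    meta <- c(.dcmElement(0x0002, 0x0000, "UL", length(meta)), meta)
    f <- file.path(dir, sprintf("IM_%04d.dcm", inst))
    con <- file(f, "wb")
    writeBin(raw(128), con)
    writeBin(charToRaw("DICM"), con)
    writeBin(c(meta, body), con)
    close(con)
    files <- c(files, f)
  }
  invisible(files)
}

.dcmParseFile <- function(path) {
  buf <- readBin(path, raw(), n = file.size(path))
  if (length(buf) < 140 || rawToChar(buf[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM marker): ", path)
  pos <- 133L
  tags <- list()
  u16 <- function(at) readBin(buf[at:(at + 1)], integer(), size = 2,
                              signed = FALSE, endian = "little")
  u32 <- function(at) readBin(buf[at:(at + 3)], integer(), size = 4,
                              endian = "little")
  while (pos + 7 <= length(buf)) {
    group <- u16(pos); elem <- u16(pos + 2L)
    vr <- rawToChar(buf[(pos + 4L):(pos + 5L)])
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      len <- u32(pos + 8L)
      valAt <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      valAt <- pos + 8L
    }
    key <- sprintf("%04X,%04X", group, elem)
    valRaw <- if (len > 0) buf[valAt:(valAt + len - 1L)] else raw(0)
    tags[[key]] <- list(vr = vr, value = valRaw)
    pos <- valAt + len
  }
  tags
}

.dcmValue <- function(tags, key, path) {
  t <- tags[[key]]
  if (is.null(t)) stop("missing DICOM tag (", key, ") in ", path)
  switch(t$vr,
    US = readBin(t$value, integer(), n = length(t$value) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    UL = readBin(t$value, integer(), n = length(t$value) / 4, size = 4,
                 endian = "little"),
    FD = readBin(t$value, double(), n = length(t$value) / 8, size = 8,
                 endian = "little"),
    OW = t$value,
    trimws(rawToChar(t$value))
  )
}

#' Read a minimal single-frame DICOM diffusion series
#'
#' Inverse of [writeDicomSeries()]: collects all \code{.dcm} files in a
#' directory, groups frames by the standard diffusion b-value tag, orders
#' slices by SliceLocation and volumes by ascending b, and returns the
#' stored 16-bit values together with the rescale slope/intercept tags
#' (never silently applied). Missing b-value or rescale tags and
#' inconsistent frame geometry raise distinct, named errors.
#'
#' @param dir directory holding the series.
#' @param extraTags optional character vector of additional tag keys
#'   (\code{"GGGG,EEEE"}) harvested verbatim into the result's attributes —
#'   the extension hook for vendor dialects.
#' @return a [DwiSeries-class].
#' @export
readDicomSeries <- function(dir, extraTags = NULL) {
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE))
  if (!length(files)) stop("no DICOM files found in ", dir)
  frames <- lapply(files, function(f) {
    tags <- .dcmParseFile(f)
    rows <- .dcmValue(tags, "0028,0010", f)
    cols <- .dcmValue(tags, "0028,0011", f)
    px <- .dcmValue(tags, "7FE0,0010", f)
    vals <- readBin(px, integer(), n = length(px) / 2, size = 2,
                    signed = FALSE, endian = "little")
    if (length(vals) != rows * cols)
      stop("pixel data length mismatch in ", f)
    extra <- if (!is.null(extraTags))
      lapply(stats::setNames(extraTags, extraTags),
             function(k) tryCatch(.dcmValue(tags, k, f), error = function(e) NULL))
    list(
      b = .dcmValue(tags, "0018,9087", f),
      sliceLoc = as.numeric(.dcmValue(tags, "0020,1041", f)),
      slope = as.numeric(.dcmValue(tags, "0028,1053", f)),
      intercept = as.numeric(.dcmValue(tags, "0028,1052", f)),
      spacing = as.numeric(strsplit(.dcmValue(tags, "0028,0030", f),
                                    "\\", fixed = TRUE)[[1]]),
      thickness = as.numeric(.dcmValue(tags, "0018,0050", f)),
      scanner = .dcmValue(tags, "0008,1010", f),
      seq = .dcmValue(tags, "0008,103E", f),
      day = as.integer(.dcmValue(tags, "0020,0011", f)),
      rep = as.integer(.dcmValue(tags, "0020,0012", f)),
      pix = matrix(vals, nrow = rows, byrow = TRUE),
      extra = extra
    )
  })
  bAll <- vapply(frames, `[[`, numeric(1), "b")
  bLevels <- sort(unique(bAll))
  locs <- sort(unique(vapply(frames, `[[`, numeric(1), "sliceLoc")))
  f1 <- frames[[1]]
  dims <- c(nrow(f1$pix), ncol(f1$pix), length(locs), length(bLevels))
  if (length(frames) != dims[3] * dims[4])
    stop("inconsistent DICOM series: ", length(frames), " frames for ",
         dims[3], " slices x ", dims[4], " b-values")
  if (length(unique(vapply(frames, function(f)
    paste(dim(f$pix), collapse = "x"), character(1)))) != 1)
    stop("inconsistent frame geometry across the DICOM series")
  if (length(unique(vapply(frames, function(f)
    paste(f$slope, f$intercept), character(1)))) != 1)
    stop("inconsistent rescale tags across the DICOM series")
  arr <- array(NA_real_, dim = dims)
  for (f in frames) {
    k <- match(f$b, bLevels)
    s <- match(f$sliceLoc, locs)
    arr[, , s, k] <- f$pix
  }
  ser <- methods::new("DwiSeries",
                      signal = arr,
                      bValues = bLevels,
                      rescaleSlope = f1$slope,
                      rescaleIntercept = f1$intercept,
                      voxelSize = c(f1$spacing, f1$thickness),
                      scannerId = f1$scanner,
                      day = f1$day,
                      repetition = f1$rep,
                      sequenceName = f1$seq)
  if (!is.null(extraTags)) attr(ser, "extraTags") <- f1$extra
  ser
}
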