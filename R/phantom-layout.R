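#' Construct a PhantomLayout
#'
#' Low-level constructor; most users want [builtinLayout()] or
#' [readPhantomLayout()].
#'
#' @param vials data.frame with columns \code{vial_id}, \code{ring},
#'   \code{pvp_percent}, \code{reference_adc}, \code{x_mm}, \code{y_mm},
#'   \code{radius_mm}, \code{s0_scale}.
#' @param phantomRadius phantom radius, mm.
#' @param slabThickness vial extent along the slice axis, mm.
#' @param temperatureC fill temperature, degrees C.
#' @param serialNumber phantom serial number the reference values belong to.
#' @return a validated [PhantomLayout-class] object.
#' @export
phantomLayout <- function(vials, phantomRadius, slabThickness,
                          temperatureC = 0, serialNumber = "unknown") {
  vials <- as.data.frame(vials)
  vials <- vials[order(vials$vial_id), , drop = FALSE]
  rownames(vials) <- NULL
  methods::new("PhantomLayout",
               vials = vials,
               phantomRadius = as.numeric(phantomRadius),
               slabThickness = as.numeric(slabThickness),
               temperatureC = as.numeric(temperatureC),
               serialNumber = as.character(serialNumber))
}

#' The packaged nominal 13-vial phantom layout
#'
#' Returns the packaged description of the CaliberMRI/NIST-style isotropic
#' diffusion phantom: one central water vial, six inner-ring and six
#' outer-ring vials whose PVP fills give six reference diffusivity levels at
#' 0 degrees C (1.109, 0.817, 0.579, 0.380, 0.220 and 0.110 um^2/ms, each
#' shared by the vial pairs/triple with equal concentration). Geometry (ring
#' radii, vial radius, slab thickness) is nominal: only relative geometry
#' matters for simulation and automated ROI placement. Vial IDs run clockwise
#' from 12 o'clock in each ring; inner-ring vials are 2, 4, 6, 8, 10, 12.
#'
#' Reference values vary with phantom serial number; supply a site-specific
#' layout file through [readPhantomLayout()] for a real phantom.
#'
#' @return a [PhantomLayout-class].
#' @examples
#' lay <- builtinLayout()
#' referenceAdc(lay, 1)   # 1.109 um2/ms, the central water vial
#' @export
builtinLayout <- function() {
  path <- system.file("extdata", "phantom_layout_nominal.cfg",
                      package = "dwiQA", mustWork = TRUE)
  readPhantomLayout(path)
}

#' Read a phantom layout from a flat key-value config file
#'
#' The layout dialect has global keys \code{phantom.serial},
#' \code{phantom.radius_mm}, \code{phantom.slab_thickness_mm},
#' \code{phantom.temperature_c} and, per vial \code{NN}, keys
#' \code{vial.NN.ring}, \code{vial.NN.pvp_percent},
#' \code{vial.NN.reference_adc}, \code{vial.NN.x_mm}, \code{vial.NN.y_mm},
#' \code{vial.NN.radius_mm} and \code{vial.NN.s0_scale}.
#'
#' @param path layout file.
#' @return a [PhantomLayout-class].
#' @seealso [writePhantomLayout()] for the inverse.
#' @export
readPhantomLayout <- function(path) {
  kv <- readFlatConfig(path)
  vkeys <- grep("^vial\\.", names(kv), value = TRUE)
  ids <- sort(unique(sub("^vial\\.([0-9]+)\\..*$", "\\1", vkeys)))
  if (!length(ids)) stop("no vial records in layout file: ", path)
  get <- function(key) {
    if (!key %in% names(kv)) stop("layout file missing key: ", key)
    kv[[key]]
  }
  vials <- do.call(rbind, lapply(ids, function(id) {
    pre <- paste0("vial.", id, ".")
    data.frame(
      vial_id = as.integer(id),
      ring = get(paste0(pre, "ring")),
      pvp_percent = as.numeric(get(paste0(pre, "pvp_percent"))),
      reference_adc = as.numeric(get(paste0(pre, "reference_adc"))),
      x_mm = as.numeric(get(paste0(pre, "x_mm"))),
      y_mm = as.numeric(get(paste0(pre, "y_mm"))),
      radius_mm = as.numeric(get(paste0(pre, "radius_mm"))),
      s0_scale = as.numeric(get(paste0(pre, "s0_scale"))),
      stringsAsFactors = FALSE
    )
  }))
  phantomLayout(vials,
                phantomRadius = as.numeric(get("phantom.radius_mm")),
                slabThickness = as.numeric(get("phantom.slab_thickness_mm")),
                temperatureC = as.numeric(get("phantom.temperature_c")),
                serialNumber = get("phantom.serial"))
}

#' Write a phantom layout to the flat key-value dialect
#'
#' @param layout a [PhantomLayout-class].
#' @param path file to write.
#' @return \code{path}, invisibly.
#' @export
writePhantomLayout <- function(layout, path) {
  stopifnot(methods::is(layout, "PhantomLayout"))
  v <- layout@vials
  kv <- c(
    phantom.serial = layout@serialNumber,
    phantom.radius_mm = format(layout@phantomRadius),
    phantom.slab_thickness_mm = format(layout@slabThickness),
    phantom.temperature_c = format(layout@temperatureC)
  )
  for (i in seq_len(nrow(v))) {
    pre <- sprintf("vial.%02d.", v$vial_id[i])
    rec <- c(ring = v$ring[i],
             pvp_percent = format(v$pvp_percent[i]),
             reference_adc = format(v$reference_adc[i]),
             x_mm = format(v$x_mm[i]),
             y_mm = format(v$y_mm[i]),
             radius_mm = format(v$radius_mm[i]),
             s0_scale = format(v$s0_scale[i]))
    names(rec) <- paste0(pre, names(rec))
    kv <- c(kv, rec)
  }
  writeFlatConfig(kv, path, header = "phantom layout")
}

#' @describeIn dwiQA-generics reference ADC (um^2/ms) of one vial; unknown
#'   vial IDs raise a lookup error.
#' @export
setMethod("referenceAdc", "PhantomLayout", function(object, vialId) {
  vialId <- as.integer(vialId)
  stopifnot(length(vialId) >= 1)
  idx <- match(vialId, object@vials$vial_id)
  if (anyNA(idx))
    stop("unknown vial_id: ", paste(vialId[is.na(idx)], collapse = ", "))
  object@vials$reference_adc[idx]
})
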