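#' Create a simulation configuration
#'
#' Defaults describe the standardized phantom acquisition the conformance
#' battery expects: four b-values (0, 500, 900, 2000 s/mm^2), Rician noise
#' calibrated to SNR 75 at b = 0 in the central water vial, and an image grid
#' (1 x 1 x 4 mm voxels, 176 x 176 x 11) that covers the phantom with the
#' vial slab centered on the middle slices. The two-b-value variant used by
#' anatomy-specific protocols is obtained by fitting a subset (see
#' [fitAdcMap()]), not by changing the acquisition.
#'
#' @param bValues b-values, s/mm^2 (sorted ascending internally).
#' @param s0 baseline b = 0 signal of the central water vial, arbitrary units.
#' @param snrB0 target SNR (mean/SD) at b = 0 in a uniform water region. The
#'   Gaussian channel SD is \code{s0 / snrB0}; for Rician noise the empirical
#'   magnitude-image SNR then matches the target to within a few percent at
#'   SNR >> 1.
#' @param noiseModel \code{"none"}, \code{"gaussian"} or \code{"rician"}
#'   (zero-mean Gaussian noise of equal SD on real and imaginary channels,
#'   then magnitude).
#' @param scannerBiasPercent named numeric: multiplicative ADC offset (%) per
#'   scanner identifier; scanners not listed get 0.
#' @param sessionDriftPercent per-day multiplicative ADC offset (%).
#' @param voxelSize numeric(3), mm (row, col, slice).
#' @param matrixSize integer(3): rows, cols, slices.
#' @param seed master seed; all derived noise streams are deterministic
#'   functions of (seed, scanner, day, repetition).
#' @param rescaleSlope,rescaleIntercept stored-value encoding written into
#'   the generated series (physical = stored * slope + intercept).
#' @param shadingPercent amplitude (%) of an optional low-order radial
#'   multiplicative shading field; 0 (default) disables it. Non-physical,
#'   intended only for robustness experiments.
#' @return a [SimulationConfig-class].
#' @export
simConfig <- function(bValues = c(0, 500, 900, 2000),
                      s0 = 1000,
                      snrB0 = 75,
                      noiseModel = c("rician", "gaussian", "none"),
                      scannerBiasPercent = numeric(0),
                      sessionDriftPercent = 0,
                      voxelSize = c(1, 1, 4),
                      matrixSize = c(176L, 176L, 11L),
                      seed = 1L,
                      rescaleSlope = 1,
                      rescaleIntercept = 0,
                      shadingPercent = 0) {
  noiseModel <- match.arg(noiseModel)
  methods::new("SimulationConfig",
               bValues = sort(as.numeric(bValues)),
               s0 = as.numeric(s0),
               snrB0 = as.numeric(snrB0),
               noiseModel = noiseModel,
               scannerBiasPercent = scannerBiasPercent,
               sessionDriftPercent = as.numeric(sessionDriftPercent),
               voxelSize = as.numeric(voxelSize),
               matrixSize = as.integer(matrixSize),
               seed = as.integer(seed),
               rescaleSlope = as.numeric(rescaleSlope),
               rescaleIntercept = as.numeric(rescaleIntercept),
               shadingPercent = as.numeric(shadingPercent))
}

## Physical coordinates of voxel centers. Convention: 0-based indices,
## volume axis at the grid center; x (mm) along columns, y along rows with
## +y towards row 1 (top), z along slices.
gridCoords <- function(matrixSize, voxelSize) {
  nr <- matrixSize[1]; nc <- matrixSize[2]; ns <- matrixSize[3]
  list(
    x = (seq_len(nc) - (nc + 1) / 2) * voxelSize[2],
    y = ((nr + 1) / 2 - seq_len(nr)) * voxelSize[1],
    z = (seq_len(ns) - (ns + 1) / 2) * voxelSize[3]
  )
}

## In-plane logical footprint (rows x cols) of a circle, pixel-center rule.
circleFootprint <- function(matrixSize, voxelSize, cx, cy, radius) {
  g <- gridCoords(matrixSize, voxelSize)
  dx2 <- outer((g$y - cy)^2, (g$x - cx)^2, "+")
  dx2 <= radius^2
}

## Deterministic per-series seed below 2^31, derived from the master seed
## and the (scanner, day, repetition) identity.
deriveSeed <- function(seed, scannerId, day, repetition) {
  h <- sum(utf8ToInt(as.character(scannerId)) * seq_along(utf8ToInt(as.character(scannerId))))
  val <- (as.double(seed) * 48271 + h * 20011 + day * 1299709 +
            repetition * 15485863) %% 2147483629
  as.integer(val) + 1L
}

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

applyNoise <- function(signal, sigma, noiseModel) {
  if (noiseModel == "none" || sigma == 0) return(signal)
  n <- length(signal)
  if (noiseModel == "gaussian") {
    signal + stats::rnorm(n, sd = sigma)
  } else { # rician: equal-SD Gaussian noise on real and imaginary channels
    re <- signal + stats::rnorm(n, sd = sigma)
    im <- stats::rnorm(n, sd = sigma)
    array(sqrt(re^2 + im^2), dim = dim(signal))
  }
}

shadingField <- function(matrixSize, voxelSize, amplitudePercent, rmax) {
  if (amplitudePercent == 0) return(NULL)
  g <- gridCoords(matrixSize, voxelSize)
  r2 <- outer(g$y^2, g$x^2, "+") / rmax^2
  1 + amplitudePercent / 100 * (0.5 - r2)
}

## Shared synthesis: paints mono-exponential decay into region masks, adds
## background, shading, noise, and encodes stored values.
synthesizeSeries <- function(regions, config, scannerId, day, repetition,
                             sequenceName, rmax) {
  ms <- config@matrixSize
  b <- config@bValues
  nb <- length(b)
  background <- 0.001 * config@s0
  vol <- array(background, dim = c(ms, nb))
  shade <- shadingField(ms, config@voxelSize, config@shadingPercent, rmax)
  for (reg in regions) {
    ## reg: list(inplane = rows x cols logical OR mask3d, slices, s0, adc)
    for (k in seq_len(nb)) {
      s <- reg$s0 * exp(-b[k] * reg$adc * 1e-3)  # adc um2/ms -> mm2/s
      if (!is.null(reg$mask3d)) {
        idx <- which(reg$mask3d)
        plane <- ms[1] * ms[2] * ms[3]
        vol[idx + (k - 1L) * plane] <- s
      } else {
        for (sl in reg$slices) {
          plane <- vol[, , sl, k]
          plane[reg$inplane] <- s
          vol[, , sl, k] <- plane
        }
      }
    }
  }
  if (!is.null(shade))
    vol <- vol * array(rep(shade, ms[3] * nb), dim = dim(vol))
  sigma <- if (config@noiseModel == "none") 0 else config@s0 / config@snrB0
  vol <- withSeed(deriveSeed(config@seed, scannerId, day, repetition),
                  applyNoise(vol, sigma, config@noiseModel))
  stored <- encodeRescale(vol, config@rescaleSlope, config@rescaleIntercept)
  methods::new("DwiSeries",
               signal = stored,
               bValues = b,
               rescaleSlope = config@rescaleSlope,
               rescaleIntercept = config@rescaleIntercept,
               voxelSize = config@voxelSize,
               scannerId = as.character(scannerId),
               day = as.integer(day),
               repetition = as.integer(repetition),
               sequenceName = sequenceName)
}

slabSlices <- function(config, slabThickness) {
  g <- gridCoords(config@matrixSize, config@voxelSize)
  which(abs(g$z) <= slabThickness / 2)
}

#' Simulate one phantom diffusion series
#'
#' Paints each vial footprint with mono-exponential decay
#' \eqn{S(b) = S_0 \exp(-b \cdot ADC)} at the vial's reference diffusivity
#' (or an override), with the vial's relative b = 0 signal taken from the
#' layout's \code{s0_scale} column, background at 0.1% of \code{s0}, then
#' applies the configured noise model and rescale encoding. Scanner bias
#' (from \code{config}, matched by \code{scannerId}) and session drift are
#' applied multiplicatively to every vial ADC before synthesis.
#'
#' @param layout a [PhantomLayout-class].
#' @param config a [SimulationConfig-class].
#' @param adcOverrides optional named numeric, um^2/ms, replacing the
#'   reference ADC of the named vial IDs.
#' @param scannerId,day,repetition provenance labels (also select the bias,
#'   drift and noise stream).
#' @param sequenceName provenance label, default \code{"qiba_epi"}.
#' @return a [DwiSeries-class].
#' @examples
#' lay <- builtinLayout()
#' cfg <- simConfig(noiseModel = "none", matrixSize = c(96L, 96L, 5L),
#'                  voxelSize = c(2, 2, 4))
#' ser <- simulatePhantomSeries(lay, cfg)
#' @export
simulatePhantomSeries <- function(layout, config, adcOverrides = NULL,
                                  scannerId = "A", day = 1L, repetition = 1L,
                                  sequenceName = "qiba_epi") {
  stopifnot(methods::is(layout, "PhantomLayout"),
            methods::is(config, "SimulationConfig"))
  ms <- config@matrixSize
  vs <- config@voxelSize
  fovx <- ms[2] * vs[2] / 2
  fovy <- ms[1] * vs[1] / 2
  v <- layout@vials
  out <- abs(v$x_mm) + v$radius_mm > fovx | abs(v$y_mm) + v$radius_mm > fovy
  if (any(out))
    stop("vial footprint outside the image matrix for vial(s): ",
         paste(v$vial_id[out], collapse = ", "))
  slices <- slabSlices(config, layout@slabThickness)
  if (!length(slices))
    stop("no slices intersect the phantom slab; increase matrix or slab")
  bias <- scannerBiasFor(config, scannerId)
  drift <- (1 + config@sessionDriftPercent / 100)^(as.integer(day) - 1L)
  regions <- lapply(seq_len(nrow(v)), function(i) {
    adc <- v$reference_adc[i]
    if (!is.null(adcOverrides)) {
      ov <- adcOverrides[as.character(v$vial_id[i])]
      if (!is.na(ov)) adc <- as.numeric(ov)
    }
    list(inplane = circleFootprint(ms, vs, v$x_mm[i], v$y_mm[i], v$radius_mm[i]),
         slices = slices,
         s0 = config@s0 * v$s0_scale[i],
         adc = adc * (1 + bias / 100) * drift)
  })
  synthesizeSeries(regions, config, scannerId, day, repetition,
                   sequenceName, rmax = layout@phantomRadius)
}

scannerBiasFor <- function(config, scannerId) {
  b <- config@scannerBiasPercent
  if (length(b) && as.character(scannerId) %in% names(b))
    as.numeric(b[[as.character(scannerId)]])
  else 0
}

#' Simulate a repetition/day/scanner-structured phantom study
#'
#' Generates one series per (scanner, day, repetition) combination with the
#' configured per-scanner bias and per-day drift applied to every vial ADC
#' before synthesis. Noise streams are derived deterministically from the
#' master seed and the series identity, so repetitions differ while the
#' whole study is reproducible.
#'
#' @param layout a [PhantomLayout-class].
#' @param config a [SimulationConfig-class].
#' @param scanners character vector of scanner identifiers.
#' @param days,repetitions number of consecutive days and same-day
#'   repetitions per scanner.
#' @param ... passed on to [simulatePhantomSeries()].
#' @return named list of [DwiSeries-class] objects
#'   (\code{"<scanner>_d<day>_r<rep>"}).
#' @export
simulateStudy <- function(layout, config, scanners = c("A", "B", "C"),
                          days = 1L, repetitions = 4L, ...) {
  stopifnot(length(scanners) >= 1, days >= 1, repetitions >= 1)
  out <- list()
  for (sc in scanners) for (d in seq_len(days)) for (r in seq_len(repetitions)) {
    key <- sprintf("%s_d%d_r%d", sc, d, r)
    out[[key]] <- simulatePhantomSeries(layout, config,
                                        scannerId = sc, day = d,
                                        repetition = r, ...)
  }
  out
}

#' Simulate a toy multi-organ volume with aligned masks
#'
#' Stand-in for in vivo acquisitions: each organ is an ellipsoid or box
#' decaying mono-exponentially at the organ's ADC, on a near-zero background.
#' Returned masks are aligned to the series grid; an organ whose continuous
#' extent crosses the field of view is clipped and its mask carries
#' \code{attr(mask, "truncated") = TRUE}, the sentinel consumed by
#' [organMaskStats()] to exclude organs not fully contained in the FOV.
#'
#' @param organSpecs list of specs, each a list with \code{label},
#'   \code{adc} (um^2/ms), \code{center_mm} (x, y, z), \code{semiaxes_mm}
#'   (x, y, z half-extents), optional \code{shape} (\code{"ellipsoid"},
#'   default, or \code{"box"}) and optional \code{s0_scale}.
#' @param config a [SimulationConfig-class].
#' @param scannerId,day,repetition,sequenceName provenance labels.
#' @return list with elements \code{series} ([DwiSeries-class]) and
#'   \code{masks} (named list of 3-D logical arrays with the truncation
#'   attribute). Overlapping organ masks raise an error.
#' @export
simulateOrganVolume <- function(organSpecs, config,
                                scannerId = "A", day = 1L, repetition = 1L,
                                sequenceName = "consortium") {
  stopifnot(methods::is(config, "SimulationConfig"), length(organSpecs) >= 1)
  ms <- config@matrixSize
  vs <- config@voxelSize
  g <- gridCoords(ms, vs)
  fov <- c(x = ms[2] * vs[2] / 2, y = ms[1] * vs[1] / 2, z = ms[3] * vs[3] / 2)
  masks <- list()
  regions <- list()
  for (spec in organSpecs) {
    shape <- if (is.null(spec$shape)) "ellipsoid" else spec$shape
    ctr <- spec$center_mm; ax <- spec$semiaxes_mm
    m <- array(FALSE, dim = ms)
    for (sl in seq_len(ms[3])) {
      dz <- (g$z[sl] - ctr[3]) / ax[3]
      if (shape == "box") {
        if (abs(g$z[sl] - ctr[3]) > ax[3]) next
        inp <- outer(abs(g$y - ctr[2]) <= ax[2], abs(g$x - ctr[1]) <= ax[1], "&")
      } else {
        if (abs(dz) > 1) next
        d2 <- outer(((g$y - ctr[2]) / ax[2])^2, ((g$x - ctr[1]) / ax[1])^2, "+")
        inp <- d2 <= 1 - dz^2
      }
      m[, , sl] <- inp
    }
    if (!any(m)) stop("organ '", spec$label, "' produced an empty mask")
    truncated <- any(abs(ctr + ax) > fov) || any(abs(ctr - ax) > fov)
    attr(m, "truncated") <- truncated
    masks[[spec$label]] <- m
    s0s <- if (is.null(spec$s0_scale)) 1 else spec$s0_scale
    regions[[spec$label]] <- list(mask3d = m, s0 = config@s0 * s0s,
                                  adc = spec$adc)
  }
  ## disjointness
  tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  if (any(tot > 1L)) stop("organ masks overlap")
  series <- synthesizeSeries(regions, config, scannerId, day, repetition,
                             sequenceName, rmax = max(fov))
  list(series = series, masks = masks)
}
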