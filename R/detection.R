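## Spectral detection and mask-cleaning stages.

#' Five-condition spectral detection rule
#'
#' Applies the calibrated band rule for floating Sargassum on the 0--1
#' surface-reflectance scale:
#' \deqn{(b8A < 0.07) \wedge (b04 < 0.1) \wedge (b11 < 0.05) \wedge
#'       (b04 < b8A) \wedge (b04 < b08)}
#' All inequalities are strict; a pixel sitting exactly on a threshold
#' fails. The first three conditions bound the overall brightness (dark
#' water background, no clouds/land), the last two require the red-edge
#' contrast of floating vegetation (red reflectance below both NIR
#' bands) that separates rafts from clear water, where red exceeds NIR.
#' Nodata pixels are never detected.
#'
#' @param scene a \code{\linkS4class{Scene}} with bands b04, b08, b8A, b11
#' @param params a \code{\linkS4class{DetectionParams}}
#' @return a \code{\linkS4class{DetectionMask}} with stages \code{"eq1"}
#' @export
eq1Mask <- function(scene, params = DetectionParams()) {
  b04 <- sceneBand(scene, "b04"); b08 <- sceneBand(scene, "b08")
  b8A <- sceneBand(scene, "b8A"); b11 <- sceneBand(scene, "b11")
  v <- (b8A < params@tB8A) & (b04 < params@tB04) & (b11 < params@tB11) &
    (b04 < b8A) & (b04 < b08)
  v[scene@nodata] <- FALSE
  DetectionMask(v, stages = "eq1", sceneRef = scene@tileId)
}

#' Floating Algae Index
#'
#' FAI is the NIR reflectance minus a linear baseline interpolated
#' between the red and SWIR bands at the NIR wavelength:
#' \deqn{FAI = R_{nir} - R_{red} - (R_{swir} - R_{red})
#'       \frac{\lambda_{nir} - \lambda_{red}}{\lambda_{swir} - \lambda_{red}}}
#' Positive values mark the vegetation red edge of floating algae. For
#' Landsat-8 OLI the band centers are (655, 865, 1609) nm; for the
#' Sentinel-2 b04/b8A/b11 mapping (665, 865, 1610) nm.
#'
#' @param scene a \code{\linkS4class{Scene}}; Landsat-style scenes use
#'   bands \code{red, nir, swir}, Sentinel-style \code{b04, b8A, b11}
#' @param wavelengths numeric(3) increasing (red, nir, swir) centers, nm;
#'   default chosen from the scene's sensor tag
#' @return a \code{\linkS4class{FAIRaster}} (NA where nodata)
#' @export
computeFAI <- function(scene, wavelengths = NULL) {
  if (is.null(wavelengths))
    wavelengths <- if (scene@sensor == "L8") c(655, 865, 1609)
                   else c(665, 865, 1610)
  if (length(wavelengths) != 3L ||
      !(wavelengths[1L] < wavelengths[2L] && wavelengths[2L] < wavelengths[3L]))
    stop("parameter error: wavelengths must be increasing (red, nir, swir)",
         call. = FALSE)
  nm <- names(sceneBands(scene))
  if (all(c("red", "nir", "swir") %in% nm)) {
    r <- sceneBand(scene, "red"); n <- sceneBand(scene, "nir")
    s <- sceneBand(scene, "swir")
  } else {
    r <- sceneBand(scene, "b04"); n <- sceneBand(scene, "b8A")
    s <- sceneBand(scene, "b11")
  }
  frac <- (wavelengths[2L] - wavelengths[1L]) /
          (wavelengths[3L] - wavelengths[1L])
  v <- n - r - (s - r) * frac
  v[scene@nodata] <- NA_real_
  new("FAIRaster", values = v, wavelengths = as.numeric(wavelengths))
}

#' Remove detections in excluded scene-classification classes
#'
#' Clears mask pixels whose SCL code belongs to the excluded set
#' (default: nodata, saturated, cloud shadow, medium/high-probability
#' cloud, thin cirrus), the cloud-masking step that keeps bright cloud
#' edges from registering as rafts.
#'
#' @param mask a \code{\linkS4class{DetectionMask}}
#' @param scl an \code{\linkS4class{SCLLayer}} on the same grid
#' @param excluded integer codes to remove
#' @return the filtered mask, stages appended with \code{"scl"}
#' @export
applySCLMask <- function(mask, scl, excluded = c(0, 1, 3, 8, 9, 10)) {
  if (!identical(dim(mask@values), dim(scl@codes)))
    stop("geometry error: mask and SCL shapes differ", call. = FALSE)
  v <- mask@values & !(scl@codes %in% excluded)
  dim(v) <- dim(mask@values)
  DetectionMask(v, stages = c(mask@stages, "scl"), sceneRef = mask@sceneRef)
}

## Per-level sliding-window counts via 2-D summed-area tables; windows
## are truncated at the grid border (counts over available pixels only).
.windowCounts <- function(indicator, w) {
  nr <- nrow(indicator); nc <- ncol(indicator)
  h <- (w - 1L) / 2L
  S <- t(apply(apply(indicator, 2L, cumsum), 1L, cumsum))
  Sp <- matrix(0, nr + 1L, nc + 1L)
  Sp[-1L, -1L] <- S
  ## clamp-extend the summed-area table so truncated border windows fall
  ## out of plain submatrix differences
  ri <- pmin(pmax(seq_len(nr + 1L + 2L * h) - h, 1L), nr + 1L)
  ci <- pmin(pmax(seq_len(nc + 1L + 2L * h) - h, 1L), nc + 1L)
  E <- Sp[ri, ci, drop = FALSE]
  r2 <- (2L * h + 2L):(nr + 2L * h + 1L); r1 <- seq_len(nr)
  c2 <- (2L * h + 2L):(nc + 2L * h + 1L); c1 <- seq_len(nc)
  E[r2, c2, drop = FALSE] - E[r1, c2, drop = FALSE] -
    E[r2, c1, drop = FALSE] + E[r1, c1, drop = FALSE]
}

#' Local-entropy texture filter
#'
#' The b8A band is quantized into Q equal-width levels over a fixed
#' reflectance interval (default the nominal 0--1 scale); for every
#' pixel the Shannon entropy (bits) of the level histogram inside a
#' w-by-w window is computed, and detections in high-entropy
#' neighborhoods (H > entropyMax) are removed. Calm water and coherent
#' rafts are spectrally uniform (low entropy) while glint and broken
#' cloud edges are texture-rich (high entropy). The quantization
#' interval is fixed rather than scene-relative so the level width
#' (about 0.03 reflectance at the defaults) stays above the radiometric
#' noise floor: on a low-dynamic-range open-water scene a scene-relative
#' quantization would resolve pure sensor noise into many levels and
#' read uniform water as high-entropy texture. Windows are truncated at
#' the grid border; nodata pixels do not contribute.
#'
#' @param mask a \code{\linkS4class{DetectionMask}}
#' @param scene the source \code{\linkS4class{Scene}} (provides b8A)
#' @param params a \code{\linkS4class{DetectionParams}} (window, levels,
#'   cutoff)
#' @return the filtered mask, stages appended with \code{"entropy"}
#' @export
entropyFilter <- function(mask, scene, params = DetectionParams()) {
  H <- localEntropy(sceneBand(scene, "b8A"), scene@nodata,
                    w = params@entropyWindow, Q = params@entropyLevels,
                    range = params@entropyRange)
  v <- mask@values & !(H > params@entropyMax)
  v[scene@nodata] <- FALSE
  DetectionMask(v, stages = c(mask@stages, "entropy"),
                sceneRef = mask@sceneRef)
}

#' Sliding-window Shannon entropy of a quantized band
#'
#' @param band numeric matrix
#' @param nodata logical matrix (TRUE = invalid); invalid pixels carry
#'   no level and do not contribute to any window histogram
#' @param w odd window side, pixels
#' @param Q number of equal-width quantization levels
#' @param range interval quantized into the Q levels; NULL uses the
#'   valid min--max of the band (scene-relative)
#' @return matrix of entropies in bits (0 for windows with no valid pixel)
#' @export
localEntropy <- function(band, nodata = NULL, w = 5, Q = 32,
                         range = c(0, 1)) {
  if (is.null(nodata)) nodata <- matrix(FALSE, nrow(band), ncol(band))
  valid <- !nodata
  if (!any(valid))
    stop("degenerate input: all pixels are nodata", call. = FALSE)
  rng <- if (is.null(range)) base::range(band[valid]) else range
  if (rng[2L] > rng[1L]) {
    lev <- pmin(pmax(floor((band - rng[1L]) / (rng[2L] - rng[1L]) * Q), 0L),
                Q - 1L)
  } else {
    lev <- matrix(0L, nrow(band), ncol(band))
  }
  lev[!valid] <- NA_integer_
  nr <- nrow(band); nc <- ncol(band)
  total <- .windowCounts(matrix(as.numeric(valid), nr, nc), w)
  Hsum <- matrix(0, nr, nc)
  for (q in sort(unique(lev[valid]))) {
    cnt <- .windowCounts(matrix(as.numeric(!is.na(lev) & lev == q), nr, nc), w)
    p <- ifelse(total > 0, cnt / total, 0)
    Hsum <- Hsum - ifelse(p > 0, p * log2(p), 0)
  }
  Hsum
}

#' Minimum-component-size denoising
#'
#' Removes connected components of fewer than \code{minSize} pixels
#' (inclusive threshold: a component of exactly \code{minSize} pixels
#' survives). Speckle-sized single-pixel detections are
#' indistinguishable from sensor noise at 20 m and are dropped by the
#' default of 2.
#'
#' @param mask a \code{\linkS4class{DetectionMask}}
#' @param params a \code{\linkS4class{DetectionParams}} (minSize,
#'   connectivity)
#' @return the filtered mask, stages appended with \code{"minsize"}
#' @export
minSizeFilter <- function(mask, params = DetectionParams()) {
  lab <- labelComponents(mask@values, params@connectivity)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- lab > 0L & sizes[pmax(lab, 1L)] >= params@minSize
    v <- matrix(keep, nrow(lab), ncol(lab))
  } else {
    v <- mask@values
  }
  DetectionMask(v, stages = c(mask@stages, "minsize"),
                sceneRef = mask@sceneRef)
}
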