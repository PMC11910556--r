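#' @import methods
NULL

setOldClass(c("POSIXct", "POSIXt"))

.checkTransform <- function(tr) {
  if (!is.numeric(tr) || length(tr) != 4L)
    return("transform must be numeric(4): x0, y0, dx, dy")
  if (anyNA(tr) || any(!is.finite(tr)))
    return("transform must be finite")
  if (tr[3L] <= 0 || tr[4L] <= 0)
    return("pixel width and height must be strictly positive")
  NULL
}

#' Scene: co-registered surface-reflectance band grids
#'
#' Holds the reflectance bands a detection run needs (Sentinel-2-style
#' \code{b02,b03,b04,b05,b08,b8A,b11} or Landsat-style
#' \code{red,nir,swir}), each a matrix on one common grid, together with
#' an affine georeference, a projected CRS identifier, a nodata mask and
#' acquisition metadata.
#'
#' Reflectance is unitless on the 0--1 scale (values in [-0.1, 1.5] are
#' accepted to allow small atmospheric-correction overshoot). The
#' transform is \code{c(x0, y0, dx, dy)}: \code{(x0, y0)} is the
#' projected coordinate of the upper-left corner of pixel (1,1), and
#' \code{dx, dy > 0} are pixel width/height in meters (north-up grid; x
#' grows with column, y shrinks with row).
#'
#' @slot bands named list of numeric matrices, one per band
#' @slot transform numeric(4) \code{c(x0, y0, dx, dy)}
#' @slot crs projected CRS identifier, e.g. \code{"EPSG:32616"}
#' @slot nodata logical matrix, TRUE where the pixel carries no data
#' @slot datetime acquisition time (UTC)
#' @slot tileId MGRS granule identifier, e.g. \code{"T16QDJ"}
#' @slot sensor \code{"S2"} or \code{"L8"}
#' @export
setClass("Scene",
  representation(bands = "list", transform = "numeric", crs = "character",
                 nodata = "matrix", datetime = "POSIXct",
                 tileId = "character", sensor = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@bands) == 0L) msgs <- c(msgs, "at least one band required")
    if (is.null(names(object@bands)) || any(!nzchar(names(object@bands))))
      msgs <- c(msgs, "bands must be named")
    dims <- lapply(object@bands, dim)
    if (length(unique(dims)) > 1L) msgs <- c(msgs, "all bands must share one shape")
    if (!identical(dim(object@nodata), dims[[1L]]))
      msgs <- c(msgs, "nodata mask must share the band shape")
    if (!is.logical(object@nodata)) msgs <- c(msgs, "nodata must be logical")
    tm <- .checkTransform(object@transform)
    if (!is.null(tm)) msgs <- c(msgs, tm)
    ok <- !object@nodata
    for (b in object@bands) {
      v <- b[ok]
      if (anyNA(v) || any(!is.finite(v)) || any(v < -0.1) || any(v > 1.5)) {
        msgs <- c(msgs, "valid reflectance must be finite and in [-0.1, 1.5]")
        break
      }
    }
    if (!object@sensor %in% c("S2", "L8"))
      msgs <- c(msgs, "sensor must be 'S2' or 'L8'")
    if (length(msgs)) msgs else TRUE
  })

#' Sen2Cor scene-classification layer
#'
#' Per-pixel integer class codes with Sen2Cor SCL semantics:
#' 0 nodata, 1 saturated, 2 dark, 3 cloud shadow, 4 vegetation, 5 bare,
#' 6 water, 7 unclassified, 8 cloud medium prob., 9 cloud high prob.,
#' 10 thin cirrus, 11 snow.
#'
#' @slot codes integer matrix with values in 0..11
#' @slot transform numeric(4), as in \code{\linkS4class{Scene}}
#' @slot crs CRS identifier
#' @export
setClass("SCLLayer",
  representation(codes = "matrix", transform = "numeric", crs = "character"),
  validity = function(object) {
    msgs <- character()
    v <- object@codes
    if (anyNA(v) || any(v < 0 | v > 11) || any(v != round(v)))
      msgs <- c(msgs, "SCL codes must be integers in 0..11")
    tm <- .checkTransform(object@transform)
    if (!is.null(tm)) msgs <- c(msgs, tm)
    if (length(msgs)) msgs else TRUE
  })

#' Boolean Sargassum detection mask
#'
#' @slot values logical matrix, TRUE = Sargassum
#' @slot stages ordered character vector of applied filter stage names
#' @slot sceneRef identifier of the source scene
#' @export
setClass("DetectionMask",
  representation(values = "matrix", stages = "character", sceneRef = "character"),
  validity = function(object) {
    if (!is.logical(object@values) || anyNA(object@values))
      "values must be logical without NA" else TRUE
  })

#' Floating Algae Index raster
#'
#' @slot values numeric matrix of FAI (unitless reflectance difference);
#'   NA where input was nodata
#' @slot wavelengths numeric(3) \code{c(red, nir, swir)} band centers, nm
#' @export
setClass("FAIRaster",
  representation(values = "matrix", wavelengths = "numeric"),
  validity = function(object) {
    w <- object@wavelengths
    if (length(w) != 3L || any(!is.finite(w)) || !(w[1L] < w[2L] && w[2L] < w[3L]))
      "wavelengths must be an increasing red < nir < swir triple (nm)" else TRUE
  })

#' Detection parameters
#'
#' Thresholds of the five-condition spectral rule and parameters of the
#' cleaning stages. Defaults follow the calibrated rule
#' \code{(b8A < 0.07) & (b04 < 0.1) & (b11 < 0.05) & (b04 < b8A) & (b04 < b08)}
#' with conservative cloud-code exclusion and light denoising.
#'
#' @slot tB8A,tB04,tB11 reflectance thresholds of the rule
#' @slot excludedScl SCL codes removed from detections
#' @slot entropyWindow odd window side (pixels) for the entropy filter
#' @slot entropyLevels number of quantization levels Q
#' @slot entropyRange reflectance interval quantized into the Q levels
#'   (fixed, so the level width stays above the sensor noise floor)
#' @slot entropyMax maximum local Shannon entropy, bits
#' @slot minSize minimum connected-component size in pixels (inclusive)
#' @slot connectivity 4 or 8
#' @slot faiThreshold optional FAI cutoff; NA means report raw FAI only
#' @export
setClass("DetectionParams",
  representation(tB8A = "numeric", tB04 = "numeric", tB11 = "numeric",
                 excludedScl = "numeric", entropyWindow = "numeric",
                 entropyLevels = "numeric", entropyRange = "numeric",
                 entropyMax = "numeric",
                 minSize = "numeric", connectivity = "numeric",
                 faiThreshold = "numeric"),
  validity = function(object) {
    msgs <- character()
    thr <- c(object@tB8A, object@tB04, object@tB11)
    if (length(thr) != 3L || any(!is.finite(thr)))
      msgs <- c(msgs, "thresholds must be finite scalars")
    w <- object@entropyWindow
    if (length(w) != 1L || w < 3 || w %% 2 != 1)
      msgs <- c(msgs, "entropy window must be odd and >= 3")
    if (object@entropyLevels < 2) msgs <- c(msgs, "entropy levels must be >= 2")
    er <- object@entropyRange
    if (length(er) != 2L || any(!is.finite(er)) || er[2L] <= er[1L])
      msgs <- c(msgs, "entropy range must be an increasing pair")
    if (object@minSize < 1) msgs <- c(msgs, "minimum size must be >= 1")
    if (!object@connectivity %in% c(4, 8))
      msgs <- c(msgs, "connectivity must be 4 or 8")
    if (any(!object@excludedScl %in% 0:11))
      msgs <- c(msgs, "excluded SCL codes must be in 0..11")
    if (length(msgs)) msgs else TRUE
  })

#' Study area: an ordered list of MGRS granules
#'
#' @slot tileIds unique, non-empty MGRS identifiers
#' @slot granuleSideKm nominal granule side length, km
#' @slot crs projection family label
#' @export
setClass("StudyArea",
  representation(tileIds = "character", granuleSideKm = "numeric",
                 crs = "character"),
  validity = function(object) {
    msgs <- character()
    ids <- object@tileIds
    if (length(ids) == 0L || any(!nzchar(ids)))
      msgs <- c(msgs, "tile ids must be non-empty strings")
    if (anyDuplicated(ids)) msgs <- c(msgs, "tile ids must be unique")
    bad <- !grepl("^T[0-9]{2}[C-X][A-Z]{2}$", ids)
    if (any(bad))
      msgs <- c(msgs, paste0("malformed MGRS id: ", paste(ids[bad], collapse = ", ")))
    if (length(object@granuleSideKm) != 1L || object@granuleSideKm <= 0)
      msgs <- c(msgs, "granule side must be > 0")
    if (length(msgs)) msgs else TRUE
  })

#' Coastline polylines in a projected CRS
#'
#' @slot lines list of n-by-2 coordinate matrices (x, y in meters)
#' @slot crs CRS identifier
#' @export
setClass("Coastline",
  representation(lines = "list", crs = "character"),
  validity = function(object) {
    if (length(object@lines) == 0L) return("coastline must be non-empty")
    for (l in object@lines) {
      if (!is.matrix(l) || ncol(l) != 2L || nrow(l) < 2L || any(!is.finite(l)))
        return("each polyline must be a finite n-by-2 matrix with n >= 2")
    }
    TRUE
  })

#' Multi-epoch cover classification stack
#'
#' Cover codes per epoch on one grid: 0 nodata, 1 water, 2 vegetation,
#' 3 bare. Epoch names are the labels; \code{seasons}, when non-empty,
#' tags each epoch \code{"dry"} or \code{"rainy"}.
#'
#' @slot epochs named list of integer matrices (codes 0..3)
#' @slot seasons character vector, length 0 or length(epochs)
#' @slot transform numeric(4)
#' @slot crs CRS identifier
#' @export
setClass("CoverStack",
  representation(epochs = "list", seasons = "character",
                 transform = "numeric", crs = "character"),
  validity = function(object) {
    msgs <- character()
    if (length(object@epochs) == 0L) msgs <- c(msgs, "at least one epoch required")
    dims <- unique(lapply(object@epochs, dim))
    if (length(dims) > 1L) msgs <- c(msgs, "all epochs must share one shape")
    for (e in object@epochs)
      if (anyNA(e) || any(!e %in% 0:3)) {
        msgs <- c(msgs, "cover codes must be 0 (nodata), 1 (water), 2 (vegetation), 3 (bare)")
        break
      }
    if (length(object@seasons) &&
        (length(object@seasons) != length(object@epochs) ||
         any(!object@seasons %in% c("dry", "rainy"))))
      msgs <- c(msgs, "seasons must be 'dry'/'rainy', one per epoch")
    if (length(msgs)) msgs else TRUE
  })

#' Persistent sandy-beach mask
#'
#' @slot values logical matrix, TRUE = sandy beach
#' @slot maxShoreDistanceM shoreline buffer width used, meters
#' @slot transform numeric(4)
#' @slot crs CRS identifier
#' @export
setClass("BeachMask",
  representation(values = "matrix", maxShoreDistanceM = "numeric",
                 transform = "numeric", crs = "character"),
  validity = function(object) {
    if (!is.logical(object@values)) return("values must be logical")
    if (object@maxShoreDistanceM <= 0) return("buffer must be > 0")
    TRUE
  })

#' Synthetic scene with exact ground truth
#'
#' @slot scene the generated \code{\linkS4class{Scene}}
#' @slot scl the accompanying \code{\linkS4class{SCLLayer}}
#' @slot truth logical matrix, TRUE at detectable planted raft pixels
#' @slot seed integer seed the scene was generated from
#' @export
setClass("SyntheticScene",
  representation(scene = "Scene", scl = "SCLLayer", truth = "matrix",
                 seed = "integer"),
  validity = function(object) {
    d <- dim(object@scene@bands[[1L]])
    if (!identical(dim(object@truth), d)) return("truth must share the scene shape")
    if (!identical(dim(object@scl@codes), d)) return("SCL must share the scene shape")
    if (!is.logical(object@truth)) return("truth must be logical")
    TRUE
  })
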