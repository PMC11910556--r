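#' @include AllClasses.R
NULL

#' Construct a Scene
#'
#' @param bands named list of reflectance matrices on one grid
#' @param transform numeric(4) \code{c(x0, y0, dx, dy)}: upper-left
#'   corner and positive pixel sizes in meters
#' @param crs projected CRS identifier (e.g. \code{"EPSG:32616"})
#' @param datetime acquisition time; character is parsed as UTC
#' @param tileId MGRS granule identifier
#' @param sensor \code{"S2"} or \code{"L8"}
#' @param nodata logical matrix; defaults to all-FALSE
#' @return a validated \code{\linkS4class{Scene}}
#' @export
Scene <- function(bands, transform, crs, datetime, tileId, sensor = "S2",
                  nodata = NULL) {
  if (length(unique(lapply(bands, dim))) > 1L)
    stop("all bands must share one shape", call. = FALSE)
  if (is.null(nodata)) {
    nodata <- matrix(FALSE, nrow(bands[[1L]]), ncol(bands[[1L]]))
    for (b in bands) nodata <- nodata | !is.finite(b)
  }
  if (is.character(datetime))
    datetime <- as.POSIXct(datetime, tz = "UTC")
  bands <- lapply(bands, function(b) { b[nodata] <- 0; b })
  new("Scene", bands = bands, transform = as.numeric(transform), crs = crs,
      nodata = nodata, datetime = datetime, tileId = tileId, sensor = sensor)
}

#' Construct an SCL layer
#' @param codes integer matrix of Sen2Cor class codes (0..11)
#' @param transform numeric(4); defaults to a unit grid at the origin
#' @param crs CRS identifier
#' @return a validated \code{\linkS4class{SCLLayer}}
#' @export
SCLLayer <- function(codes, transform = c(0, 0, 1, 1), crs = "") {
  storage.mode(codes) <- "integer"
  new("SCLLayer", codes = codes, transform = as.numeric(transform), crs = crs)
}

#' Construct a DetectionMask
#' @param values logical matrix
#' @param stages character vector of applied stage names
#' @param sceneRef source scene identifier
#' @return a \code{\linkS4class{DetectionMask}}
#' @export
DetectionMask <- function(values, stages = character(), sceneRef = "") {
  new("DetectionMask", values = values, stages = stages, sceneRef = sceneRef)
}

#' Detection parameters with calibrated defaults
#'
#' @param tB8A,tB04,tB11 reflectance thresholds of the five-condition
#'   rule (defaults 0.07, 0.10, 0.05)
#' @param excludedScl SCL codes excluded from detections
#'   (default nodata, saturated, shadow, both cloud classes, cirrus)
#' @param entropyWindow odd window side for the entropy filter, pixels
#' @param entropyLevels quantization levels Q for the entropy filter
#' @param entropyRange fixed reflectance interval quantized into Q
#'   levels (default the nominal 0--1 scale, giving a level width of
#'   about 0.03 -- well above the radiometric noise floor, so uniform
#'   water or raft fields stay low-entropy)
#' @param entropyMax entropy cutoff, bits
#' @param minSize minimum connected-component size, pixels (inclusive)
#' @param connectivity 4 or 8 (default 8)
#' @param faiThreshold optional FAI cutoff; NA = report raw FAI
#' @return a validated \code{\linkS4class{DetectionParams}}
#' @export
DetectionParams <- function(tB8A = 0.07, tB04 = 0.10, tB11 = 0.05,
                            excludedScl = c(0, 1, 3, 8, 9, 10),
                            entropyWindow = 5, entropyLevels = 32,
                            entropyRange = c(0, 1),
                            entropyMax = 3.0, minSize = 2,
                            connectivity = 8, faiThreshold = NA_real_) {
  new("DetectionParams", tB8A = tB8A, tB04 = tB04, tB11 = tB11,
      excludedScl = as.numeric(excludedScl), entropyWindow = entropyWindow,
      entropyLevels = entropyLevels, entropyRange = as.numeric(entropyRange),
      entropyMax = entropyMax,
      minSize = minSize, connectivity = connectivity,
      faiThreshold = as.numeric(faiThreshold))
}

#' Construct a Coastline from polylines
#' @param lines a single n-by-2 matrix or a list of them (x, y meters)
#' @param crs CRS identifier
#' @return a validated \code{\linkS4class{Coastline}}
#' @export
Coastline <- function(lines, crs = "") {
  if (is.matrix(lines)) lines <- list(lines)
  new("Coastline", lines = lines, crs = crs)
}

#' Construct a CoverStack
#' @param epochs named list of cover-code matrices (0 nodata, 1 water,
#'   2 vegetation, 3 bare)
#' @param seasons optional \code{"dry"}/\code{"rainy"} tag per epoch
#' @param transform numeric(4)
#' @param crs CRS identifier
#' @return a validated \code{\linkS4class{CoverStack}}
#' @export
CoverStack <- function(epochs, seasons = character(),
                       transform = c(0, 0, 1, 1), crs = "") {
  epochs <- lapply(epochs, function(e) { storage.mode(e) <- "integer"; e })
  if (is.null(names(epochs)))
    names(epochs) <- paste0("epoch", seq_along(epochs))
  new("CoverStack", epochs = epochs, seasons = seasons,
      transform = as.numeric(transform), crs = crs)
}

#' Construct a StudyArea
#' @param tileIds MGRS identifiers
#' @param granuleSideKm nominal granule side, km
#' @param crs projection family label
#' @return a validated \code{\linkS4class{StudyArea}}
#' @export
StudyArea <- function(tileIds, granuleSideKm = 109.8, crs = "UTM/WGS84") {
  new("StudyArea", tileIds = as.character(tileIds),
      granuleSideKm = granuleSideKm, crs = crs)
}
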