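#' @include AllClasses.R
NULL

#' @rdname accessors
#' @export
setGeneric("sceneBands", function(x) standardGeneric("sceneBands"))
#' @rdname accessors
#' @export
setGeneric("sceneBand", function(x, band) standardGeneric("sceneBand"))
#' @rdname accessors
#' @export
setGeneric("geoTransform", function(x) standardGeneric("geoTransform"))
#' @rdname accessors
#' @export
setGeneric("crsId", function(x) standardGeneric("crsId"))
#' @rdname accessors
#' @export
setGeneric("nodataMask", function(x) standardGeneric("nodataMask"))
#' @rdname accessors
#' @export
setGeneric("acquisitionTime", function(x) standardGeneric("acquisitionTime"))
#' @rdname accessors
#' @export
setGeneric("tileId", function(x) standardGeneric("tileId"))
#' @rdname accessors
#' @export
setGeneric("sensorTag", function(x) standardGeneric("sensorTag"))
#' @rdname accessors
#' @export
setGeneric("sclCodes", function(x) standardGeneric("sclCodes"))
#' @rdname accessors
#' @export
setGeneric("maskValues", function(x) standardGeneric("maskValues"))
#' @rdname accessors
#' @export
setGeneric("maskStages", function(x) standardGeneric("maskStages"))
#' @rdname accessors
#' @export
setGeneric("faiValues", function(x) standardGeneric("faiValues"))
#' @rdname accessors
#' @export
setGeneric("faiWavelengths", function(x) standardGeneric("faiWavelengths"))
#' @rdname accessors
#' @export
setGeneric("tileIds", function(x) standardGeneric("tileIds"))
#' @rdname accessors
#' @export
setGeneric("coastLines", function(x) standardGeneric("coastLines"))
#' @rdname accessors
#' @export
setGeneric("pixelArea", function(x) standardGeneric("pixelArea"))
#' @rdname accessors
#' @export
setGeneric("truthMask", function(x) standardGeneric("truthMask"))

#' Accessors for SargassumRafts classes
#'
#' Slot access for the package's S4 objects: bands and georeferencing of
#' a \code{\linkS4class{Scene}}, codes of a \code{\linkS4class{SCLLayer}},
#' values and stage provenance of a \code{\linkS4class{DetectionMask}},
#' and so on. \code{pixelArea} returns the area of one pixel footprint in
#' square meters, invariant under translation of the transform.
#'
#' @param x an object of the documented class
#' @param band a band identifier such as \code{"b8A"}
#' @name accessors
#' @aliases sceneBands sceneBand geoTransform crsId nodataMask
#'   acquisitionTime tileId sensorTag sclCodes maskValues maskStages
#'   faiValues faiWavelengths tileIds coastLines pixelArea truthMask
NULL

setMethod("sceneBands", "Scene", function(x) x@bands)
setMethod("sceneBand", "Scene", function(x, band) {
  if (!band %in% names(x@bands))
    stop("configuration error: band '", band, "' not present in scene", call. = FALSE)
  x@bands[[band]]
})
setMethod("geoTransform", "Scene", function(x) x@transform)
setMethod("geoTransform", "SCLLayer", function(x) x@transform)
setMethod("geoTransform", "CoverStack", function(x) x@transform)
setMethod("geoTransform", "BeachMask", function(x) x@transform)
setMethod("crsId", "Scene", function(x) x@crs)
setMethod("crsId", "SCLLayer", function(x) x@crs)
setMethod("crsId", "Coastline", function(x) x@crs)
setMethod("nodataMask", "Scene", function(x) x@nodata)
setMethod("acquisitionTime", "Scene", function(x) x@datetime)
setMethod("tileId", "Scene", function(x) x@tileId)
setMethod("sensorTag", "Scene", function(x) x@sensor)
setMethod("sclCodes", "SCLLayer", function(x) x@codes)
setMethod("maskValues", "DetectionMask", function(x) x@values)
setMethod("maskStages", "DetectionMask", function(x) x@stages)
setMethod("faiValues", "FAIRaster", function(x) x@values)
setMethod("faiWavelengths", "FAIRaster", function(x) x@wavelengths)
setMethod("tileIds", "StudyArea", function(x) x@tileIds)
setMethod("coastLines", "Coastline", function(x) x@lines)
setMethod("truthMask", "SyntheticScene", function(x) x@truth)
setMethod("pixelArea", "Scene", function(x) x@transform[3L] * x@transform[4L])
setMethod("pixelArea", "SCLLayer", function(x) x@transform[3L] * x@transform[4L])

#' @export
setMethod("dim", "Scene", function(x) dim(x@bands[[1L]]))
#' @export
setMethod("dim", "SCLLayer", function(x) dim(x@codes))
#' @export
setMethod("dim", "DetectionMask", function(x) dim(x@values))

setMethod("show", "Scene", function(object) {
  d <- dim(object)
  cat("Scene", object@tileId, format(object@datetime, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      sprintf("[%s]\n", object@sensor))
  cat("  ", d[1L], "x", d[2L], "pixels,", length(object@bands), "bands:",
      paste(names(object@bands), collapse = ", "), "\n")
  cat("  crs:", object@crs, " pixel:",
      object@transform[3L], "x", object@transform[4L], "m\n")
  cat("  nodata pixels:", sum(object@nodata), "\n")
})

setMethod("show", "DetectionMask", function(object) {
  d <- dim(object)
  cat("DetectionMask", d[1L], "x", d[2L], ":", sum(object@values),
      "detected pixels; stages:", paste(object@stages, collapse = " -> "), "\n")
})

setMethod("show", "SCLLayer", function(object) {
  d <- dim(object@codes)
  cat("SCLLayer", d[1L], "x", d[2L], "\n")
  tb <- table(object@codes)
  cat("  codes:", paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = " "), "\n")
})

setMethod("show", "FAIRaster", function(object) {
  d <- dim(object@values)
  rng <- range(object@values, na.rm = TRUE)
  cat(sprintf("FAIRaster %d x %d, lambda = (%g, %g, %g) nm, range [%.4g, %.4g]\n",
              d[1L], d[2L], object@wavelengths[1L], object@wavelengths[2L],
              object@wavelengths[3L], rng[1L], rng[2L]))
})

setMethod("show", "StudyArea", function(object) {
  cat("StudyArea:", length(object@tileIds), "MGRS granules of",
      object@granuleSideKm, "km side (", object@crs, ")\n")
  cat(" ", paste(object@tileIds, collapse = ", "), "\n")
})

setMethod("show", "SyntheticScene", function(object) {
  cat("SyntheticScene (seed", object@seed, "):", sum(object@truth),
      "true raft pixels\n")
  show(object@scene)
})
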