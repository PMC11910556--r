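## Fixed-order end-to-end pipeline, configuration, study area.

#' Pipeline configuration
#'
#' Bundles the detection parameters and the vector/statistics options
#' of a run. Everything is overridable from a YAML file via
#' \code{\link{loadPipelineConfig}}; the defaults are the calibrated
#' values.
#'
#' @param params a \code{\linkS4class{DetectionParams}}
#' @param binEdges distance color-scale bin edges, km
#' @param cloudCodes SCL codes counted as cloud in statistics
#' @param coastline optional \code{\linkS4class{Coastline}}
#' @param beachMask,benthicMask optional masks
#' @param compositeMode composite rendered by the run
#' @param stretch composite stretch percentiles
#' @return a pipeline config (list)
#' @export
pipelineConfig <- function(params = DetectionParams(),
                           binEdges = c(1, 5, 10),
                           cloudCodes = c(8, 9, 10),
                           coastline = NULL, beachMask = NULL,
                           benthicMask = NULL,
                           compositeMode = "false_color",
                           stretch = c(2, 98)) {
  validObject(params)
  structure(list(params = params, binEdges = binEdges,
                 cloudCodes = cloudCodes, coastline = coastline,
                 beachMask = beachMask, benthicMask = benthicMask,
                 compositeMode = compositeMode, stretch = stretch),
            class = "PipelineConfig")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: \code{thresholds} (b8A, b04, b11),
#' \code{excluded_scl}, \code{entropy} (window, levels, range, max_bits),
#' \code{min_size}, \code{connectivity}, \code{fai_threshold},
#' \code{bin_edges_km}, \code{cloud_codes}, \code{paths} (coastline,
#' beach_mask, benthic_mask). Unknown keys raise an error.
#'
#' @param path YAML file
#' @return a \code{\link{pipelineConfig}}
#' @export
loadPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("thresholds", "excluded_scl", "entropy", "min_size",
             "connectivity", "fai_threshold", "bin_edges_km", "cloud_codes",
             "paths", "composite_mode", "stretch")
  bad <- setdiff(names(y), known)
  if (length(bad))
    stop("validation error: unknown config key(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  g <- function(x, d) if (is.null(x)) d else x
  thr <- y$thresholds
  ent <- y$entropy
  params <- DetectionParams(
    tB8A = g(thr$b8A, 0.07), tB04 = g(thr$b04, 0.10), tB11 = g(thr$b11, 0.05),
    excludedScl = g(y$excluded_scl, c(0, 1, 3, 8, 9, 10)),
    entropyWindow = g(ent$window, 5), entropyLevels = g(ent$levels, 32),
    entropyRange = g(ent$range, c(0, 1)),
    entropyMax = g(ent$max_bits, 3.0), minSize = g(y$min_size, 2),
    connectivity = g(y$connectivity, 8),
    faiThreshold = g(y$fai_threshold, NA_real_))
  coast <- NULL
  if (!is.null(y$paths$coastline)) {
    if (!file.exists(y$paths$coastline))
      stop("validation error: coastline path does not exist", call. = FALSE)
    coast <- readCoastlineGeoJSON(y$paths$coastline)
  }
  bm <- NULL
  if (!is.null(y$paths$beach_mask)) {
    r <- readRasterTIFF(y$paths$beach_mask)
    bm <- round(r$values) == 1
  }
  vm <- NULL
  if (!is.null(y$paths$benthic_mask)) {
    r <- readRasterTIFF(y$paths$benthic_mask)
    vm <- round(r$values) == 1
  }
  pipelineConfig(params = params, binEdges = g(y$bin_edges_km, c(1, 5, 10)),
                 cloudCodes = g(y$cloud_codes, c(8, 9, 10)),
                 coastline = coast, beachMask = bm, benthicMask = vm,
                 compositeMode = g(y$composite_mode, "false_color"),
                 stretch = g(y$stretch, c(2, 98)))
}

#' Write/read a coastline as GeoJSON LineStrings
#'
#' Projected coordinates are written as WGS84 per RFC 7946 with the
#' projected CRS kept as a foreign member, mirroring
#' \code{\link{writeGeoJSON}}.
#'
#' @param coastline a \code{\linkS4class{Coastline}}
#' @param path file path
#' @return the path (write) or a \code{\linkS4class{Coastline}} (read)
#' @export
writeCoastlineGeoJSON <- function(coastline, path) {
  crs <- coastline@crs
  zn <- if (nzchar(crs)) .epsgZone(crs) else NULL
  feats <- lapply(coastline@lines, function(l) {
    ll <- if (is.null(zn)) l else .reprojRing(l, zn$zone, zn$north)
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(ll)), function(i)
                           c(ll[i, 1L], ll[i, 2L]))),
         properties = stats::setNames(list(), character(0)))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  if (!is.null(zn)) obj$crs_projected <- crs
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                              null = "null"), path)
  invisible(path)
}

#' @rdname writeCoastlineGeoJSON
#' @export
readCoastlineGeoJSON <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  crs <- obj$crs_projected
  zn <- if (!is.null(crs)) .epsgZone(crs) else NULL
  lines <- lapply(obj$features, function(f) {
    m <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    if (!is.null(zn)) m <- .reprojRing(m, zn$zone, zn$north, inverse = TRUE)
    colnames(m) <- c("x", "y")
    m
  })
  Coastline(lines, crs = if (is.null(crs)) "" else crs)
}

#' Run the full detection pipeline
#'
#' Fixed stage order: spectral rule -> SCL cloud mask -> entropy filter
#' -> minimum-size filter -> vectorization -> attributes -> summary.
#' Writes, under \code{outDir}: \code{rafts.geojson},
#' \code{mask.tif} (+ world file and sidecar), \code{composite.png}
#' (skipped when the scene lacks the composite's bands),
#' \code{summary.csv} and \code{run_params.json} (the audit sidecar with
#' the full parameter set and the stage list). On any stage error the
#' partial outputs are removed and the error is re-raised with the stage
#' name.
#'
#' @param scene a \code{\linkS4class{Scene}}
#' @param scl the matching \code{\linkS4class{SCLLayer}}
#' @param config a \code{\link{pipelineConfig}}
#' @param outDir output directory (created if needed); NULL = no files
#' @param verbose log one line per stage
#' @return list with \code{records}, \code{summary}, \code{mask},
#'   \code{paths}
#' @export
runPipeline <- function(scene, scl, config = pipelineConfig(),
                        outDir = NULL, verbose = FALSE) {
  stage <- "init"
  written <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  result <- tryCatch({
    stage <- "eq1"
    mask <- eq1Mask(scene, config$params)
    say("stage eq1: %d pixels", sum(mask@values))
    stage <- "scl"
    mask <- applySCLMask(mask, scl, config$params@excludedScl)
    say("stage scl: %d pixels", sum(mask@values))
    stage <- "entropy"
    mask <- entropyFilter(mask, scene, config$params)
    say("stage entropy: %d pixels", sum(mask@values))
    stage <- "minsize"
    mask <- minSizeFilter(mask, config$params)
    say("stage minsize: %d pixels", sum(mask@values))
    stage <- "vectorize"
    polys <- maskToPolygons(mask, scene, config$params@connectivity)
    say("stage vectorize: %d polygons", length(polys))
    stage <- "attributes"
    records <- buildRecords(polys, scene, coastline = config$coastline,
                            beachMask = config$beachMask,
                            benthicMask = config$benthicMask,
                            binEdges = config$binEdges)
    stage <- "summary"
    summ <- sceneSummary(records, scl, tileId = scene@tileId,
                         acquisitionDate = scene@datetime,
                         cloudCodes = config$cloudCodes)
    paths <- list()
    if (!is.null(outDir)) {
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      stage <- "write"
      p <- file.path(outDir, "rafts.geojson")
      writeGeoJSON(records, p); written <- c(written, p)
      paths$geojson <- p
      p <- file.path(outDir, "mask.tif")
      writeMask(mask, scene, p)
      written <- c(written, p, .worldPath(p), .sidecarPath(p))
      paths$mask <- p
      compBands <- if (config$compositeMode == "true_color")
        c("b04", "b03", "b02") else c("b8A", "b05", "b04")
      if (all(compBands %in% names(sceneBands(scene)))) {
        p <- file.path(outDir, "composite.png")
        renderComposite(scene, config$compositeMode, config$stretch, path = p)
        written <- c(written, p); paths$composite <- p
      } else {
        say("composite skipped: band(s) %s not present",
            paste(setdiff(compBands, names(sceneBands(scene))), collapse = ", "))
      }
      p <- file.path(outDir, "summary.csv")
      df <- summ
      df$acquisition_date <- format(df$acquisition_date,
                                    "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
      utils::write.csv(df, p, row.names = FALSE); written <- c(written, p)
      paths$summary <- p
      p <- file.path(outDir, "run_params.json")
      pj <- config$params
      audit <- list(
        stages = mask@stages,
        thresholds = list(b8A = pj@tB8A, b04 = pj@tB04, b11 = pj@tB11),
        excluded_scl = pj@excludedScl,
        entropy = list(window = pj@entropyWindow, levels = pj@entropyLevels,
                       range = pj@entropyRange, max_bits = pj@entropyMax),
        min_size = pj@minSize, connectivity = pj@connectivity,
        bin_edges_km = config$binEdges, cloud_codes = config$cloudCodes,
        tile_id = scene@tileId,
        acquisition_date = format(scene@datetime, "%Y-%m-%dT%H:%M:%SZ",
                                  tz = "UTC"))
      writeLines(jsonlite::toJSON(audit, auto_unbox = TRUE, digits = 10), p)
      written <- c(written, p); paths$params <- p
    }
    list(records = records, summary = summ, mask = mask, paths = paths)
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  result
}

#' Load the study-area tile configuration
#'
#' Without a path, the packaged default is loaded: the 18 Sentinel-2
#' MGRS granules covering the Mexican Caribbean and adjacent coasts of
#' Belize, Guatemala and Honduras, 109.8 km UTM/WGS84 granules.
#'
#' @param path optional YAML file with keys \code{tile_ids},
#'   \code{granule_side_km}, \code{crs}
#' @return a validated \code{\linkS4class{StudyArea}}
#' @export
loadStudyArea <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "study_area.yaml",
                        package = "SargassumRafts", mustWork = TRUE)
  y <- yaml::read_yaml(path)
  ids <- as.character(unlist(y$tile_ids))
  sa <- try(StudyArea(ids,
                      granuleSideKm = if (is.null(y$granule_side_km)) 109.8
                                      else y$granule_side_km,
                      crs = if (is.null(y$crs)) "UTM/WGS84" else y$crs),
            silent = TRUE)
  if (inherits(sa, "try-error"))
    stop("validation error: ", attr(sa, "condition")$message, call. = FALSE)
  sa
}
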