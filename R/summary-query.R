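## Scene statistics, recent-pass tables, attribute queries.

#' Cloud percentage of a scene-classification layer
#'
#' 100 x (pixels in cloud classes) / (valid pixels), where valid means
#' SCL code != 0 (nodata is excluded from the denominator). Default
#' cloud classes: medium probability (8), high probability (9), thin
#' cirrus (10).
#'
#' @param scl an \code{\linkS4class{SCLLayer}}
#' @param cloudCodes integer codes counted as cloud
#' @return percentage in [0, 100]
#' @export
cloudPercent <- function(scl, cloudCodes = c(8, 9, 10)) {
  codes <- scl@codes
  nValid <- sum(codes != 0L)
  if (nValid == 0L)
    stop("degenerate input: SCL has no valid pixels", call. = FALSE)
  100 * sum(codes %in% cloudCodes) / nValid
}

#' Per-scene summary
#'
#' Totals feeding the statistics window: summed raft area, polygon
#' count, and cloud percentage.
#'
#' @param records raft records of the scene (from
#'   \code{\link{buildRecords}})
#' @param scl the scene's \code{\linkS4class{SCLLayer}}
#' @param tileId,acquisitionDate scene metadata; default taken from the
#'   records when present
#' @param cloudCodes codes counted as cloud
#' @return one-row data.frame: tile_id, acquisition_date,
#'   total_area_km2, n_polygons, cloud_percent
#' @export
sceneSummary <- function(records, scl, tileId = NULL, acquisitionDate = NULL,
                         cloudCodes = c(8, 9, 10)) {
  if (is.null(tileId))
    tileId <- if (nrow(records)) records$tile_id[1L] else NA_character_
  if (is.null(acquisitionDate))
    acquisitionDate <- if (nrow(records)) records$acquisition_date[1L]
                       else as.POSIXct(NA)
  data.frame(
    tile_id = tileId,
    acquisition_date = acquisitionDate,
    total_area_km2 = sum(records$area_km2),
    n_polygons = nrow(records),
    cloud_percent = cloudPercent(scl, cloudCodes),
    stringsAsFactors = FALSE)
}

#' Filter raft records with the portal's query operators
#'
#' Area clauses use the operators greater-than-or-equal, less-than-
#' or-equal, and equal (equality within 1e-9 km2 absolute tolerance);
#' date clauses are inclusive at both ends and compared in UTC; an
#' optional location class restricts to one class. An empty filter
#' returns the records unchanged; ordering is preserved.
#'
#' @param records raft records data.frame
#' @param areaOp one of \code{"ge"}, \code{"le"}, \code{"eq"}, or NULL
#' @param areaKm2 area value for the clause, km2
#' @param from,to inclusive date range bounds (POSIXct or parseable
#'   character, UTC)
#' @param locationClass optional class to keep
#' @return the matching records, original order
#' @export
queryRecords <- function(records, areaOp = NULL, areaKm2 = NULL,
                         from = NULL, to = NULL, locationClass = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(areaOp)) {
    if (is.null(areaKm2) || areaKm2 < 0)
      stop("parameter error: a non-negative area value is required",
           call. = FALSE)
    keep <- keep & switch(match.arg(areaOp, c("ge", "le", "eq")),
      ge = records$area_km2 >= areaKm2,
      le = records$area_km2 <= areaKm2,
      eq = abs(records$area_km2 - areaKm2) <= 1e-9)
  }
  asUTC <- function(x) if (is.character(x)) as.POSIXct(x, tz = "UTC") else x
  from <- asUTC(from); to <- asUTC(to)
  if (!is.null(from) && !is.null(to) && from > to)
    stop("parameter error: inverted date range", call. = FALSE)
  if (!is.null(from)) keep <- keep & records$acquisition_date >= from
  if (!is.null(to)) keep <- keep & records$acquisition_date <= to
  if (!is.null(locationClass))
    keep <- keep & records$location_class == locationClass
  records[keep, , drop = FALSE]
}

#' Most recent satellite passes
#'
#' The n scene summaries with the most recent acquisition dates, sorted
#' newest first (all of them when fewer than n exist); ties on the date
#' break stably by tile id.
#'
#' @param summaries data.frame of rows from \code{\link{sceneSummary}}
#' @param n number of passes (default 10)
#' @return the ordered head of the table
#' @export
lastNTable <- function(summaries, n = 10) {
  if (n < 1) stop("parameter error: n must be >= 1", call. = FALSE)
  ord <- order(summaries$acquisition_date, summaries$tile_id,
               decreasing = c(TRUE, FALSE), method = "radix")
  out <- summaries[ord, , drop = FALSE]
  utils::head(out, n)
}
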