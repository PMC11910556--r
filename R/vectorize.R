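## Mask -> attributed raft polygons, GeoJSON/CSV serialization.

#' Convert a detection mask into raft polygons
#'
#' One polygon per connected component, its boundary traced exactly
#' along pixel edges (no smoothing) so that area is conserved and
#' rasterizing the polygons reproduces the mask. Holes are preserved.
#' Components are ordered row-major by each component's first pixel.
#'
#' @param mask a \code{\linkS4class{DetectionMask}} (or logical matrix)
#' @param scene the source \code{\linkS4class{Scene}} (georeference)
#' @param connectivity 4 or 8 (default 8)
#' @return list of components, each a list with \code{rings} (closed
#'   n-by-2 matrices in projected meters; outer ring counterclockwise,
#'   holes clockwise), \code{pixelCount}, \code{pixels} (column-major
#'   linear indices), and \code{edgeTouching}
#' @export
maskToPolygons <- function(mask, scene, connectivity = 8) {
  values <- if (is(mask, "DetectionMask")) mask@values else mask
  if (!identical(dim(values), dim(scene)))
    stop("geometry error: mask and scene shapes differ", call. = FALSE)
  tr <- scene@transform
  nr <- nrow(values); nc <- ncol(values)
  lab <- labelComponents(values, connectivity)
  n <- max(lab)
  if (n == 0L) return(list())
  comps <- vector("list", n)
  pixByLab <- split(which(lab > 0L), lab[lab > 0L])
  for (k in seq_len(n)) {
    pix <- pixByLab[[as.character(k)]]
    ringsPx <- .traceRings(pix, nr, nc, connectivity)
    rings <- lapply(ringsPx, function(rg)
      cbind(x = tr[1L] + rg[, 2L] * tr[3L], y = tr[2L] - rg[, 1L] * tr[4L]))
    i <- (pix - 1L) %% nr + 1L
    j <- (pix - 1L) %/% nr + 1L
    comps[[k]] <- list(rings = rings, pixelCount = length(pix), pixels = pix,
                       edgeTouching = any(i == 1L | i == nr | j == 1L | j == nc))
  }
  comps
}

#' Minimum distance from a raft polygon to the coastline
#'
#' Nearest-edge Euclidean distance in the projected plane between the
#' polygon boundary (or interior) and any coastline polyline; exactly 0
#' when they intersect.
#'
#' @param component a component from \code{\link{maskToPolygons}}, or a
#'   list of rings
#' @param coastline a \code{\linkS4class{Coastline}}
#' @return distance in km
#' @export
distanceToCoast <- function(component, coastline) {
  if (!is(coastline, "Coastline") || length(coastline@lines) == 0L)
    stop("contract violation: a non-empty coastline is required", call. = FALSE)
  rings <- if (!is.null(component$rings)) component$rings else component
  .ringsToLinesDist(rings, coastline@lines) / 1000
}

#' Classify a raft's detection location
#'
#' Precedence beach > other seaweed > ocean: a polygon overlapping the
#' sandy-beach mask is \code{"beach"}; otherwise one overlapping the
#' benthic-vegetation mask is \code{"other_seaweed"}; all remaining
#' rafts are \code{"ocean"}. Masks share the scene grid, so overlap is
#' evaluated on the component's pixel set.
#'
#' @param component a component from \code{\link{maskToPolygons}}
#' @param beachMask a \code{\linkS4class{BeachMask}}, logical matrix, or
#'   NULL
#' @param benthicMask logical matrix or NULL
#' @return one of \code{"ocean"}, \code{"beach"}, \code{"other_seaweed"}
#' @export
classifyLocation <- function(component, beachMask = NULL, benthicMask = NULL) {
  pix <- component$pixels
  bm <- if (is(beachMask, "BeachMask")) beachMask@values else beachMask
  if (!is.null(bm) && any(bm[pix])) return("beach")
  if (!is.null(benthicMask) && any(benthicMask[pix])) return("other_seaweed")
  "ocean"
}

.DIST_BIN_EDGES <- c(1, 5, 10)

.distanceBin <- function(d, edges = .DIST_BIN_EDGES) {
  labs <- c(paste0(c(0, edges[-length(edges)]), "-", edges), paste0(">", edges[length(edges)]))
  as.character(cut(d, breaks = c(0, edges, Inf), labels = labs,
                   include.lowest = TRUE))
}

#' Build the raft attribute table
#'
#' Assembles one record per polygon with the portal attribute schema:
#' unique id (1..n in row-major component order), acquisition date,
#' tile, pixel count, area in km2 (pixel count x pixel area), distance
#' to coast in km with its color-scale bin, location class, and an
#' \code{edge_touching} flag for rafts cut by the scene boundary.
#'
#' @param polygons output of \code{\link{maskToPolygons}}
#' @param scene the source \code{\linkS4class{Scene}}
#' @param coastline optional \code{\linkS4class{Coastline}}; without it
#'   the distance attributes are NA
#' @param beachMask,benthicMask optional masks for
#'   \code{\link{classifyLocation}}
#' @param binEdges distance color-scale bin edges, km
#' @return data.frame with a \code{geometry} list-column (rings in
#'   projected meters); the scene CRS is attached as
#'   \code{attr(, "crs")}
#' @export
buildRecords <- function(polygons, scene, coastline = NULL, beachMask = NULL,
                         benthicMask = NULL, binEdges = .DIST_BIN_EDGES) {
  if (!nzchar(scene@tileId) || is.na(scene@tileId))
    stop("configuration error: scene metadata (tile id) missing", call. = FALSE)
  n <- length(polygons)
  px <- pixelArea(scene)
  dist <- rep(NA_real_, n)
  if (!is.null(coastline) && n > 0L)
    dist <- vapply(polygons, distanceToCoast, 0.0, coastline = coastline)
  rec <- data.frame(
    id = seq_len(n),
    acquisition_date = rep(scene@datetime, length.out = n),
    tile_id = rep(scene@tileId, length.out = n),
    pixel_count = if (n) vapply(polygons, `[[`, 0L, "pixelCount") else integer(0),
    stringsAsFactors = FALSE)
  rec$area_km2 <- rec$pixel_count * px / 1e6
  rec$distance_to_coast_km <- dist
  rec$distance_bin <- ifelse(is.na(dist), NA_character_,
                             .distanceBin(dist, binEdges))
  rec$location_class <- if (n)
    vapply(polygons, classifyLocation, "", beachMask = beachMask,
           benthicMask = benthicMask) else character(0)
  rec$edge_touching <- if (n)
    vapply(polygons, `[[`, TRUE, "edgeTouching") else logical(0)
  rec$geometry <- I(lapply(polygons, `[[`, "rings"))
  attr(rec, "crs") <- scene@crs
  rec
}

## group a component's rings into (outer, holes...) sets for GeoJSON;
## returns list of list(outer = ring, holes = list of rings)
.groupRings <- function(rings) {
  area <- vapply(rings, .ringSignedArea, 0.0)
  pos <- which(area > 0); neg <- which(area < 0)
  if (length(pos) == 0L) pos <- which.max(abs(area))  # defensive
  groups <- lapply(pos, function(p) list(outer = rings[[p]], holes = list()))
  for (h in neg) {
    hr <- rings[[h]]
    ## representative point just inside the hole: midpoint of first edge,
    ## offset to the side away from the component interior
    mid <- (hr[1L, ] + hr[2L, ]) / 2
    dirv <- hr[2L, ] - hr[1L, ]
    nrm <- c(-dirv[2L], dirv[1L]) / sqrt(sum(dirv^2))
    eps <- sqrt(sum(dirv^2)) * 0.25
    cand <- rbind(mid + nrm * eps, mid - nrm * eps)
    inhole <- !.pointInRings(cand, rings)
    pt <- cand[which(inhole)[1L], , drop = FALSE]
    owner <- which(vapply(pos, function(p)
      .pointInRings(pt, rings[p]), TRUE))[1L]
    if (is.na(owner)) owner <- 1L
    groups[[owner]]$holes <- c(groups[[owner]]$holes, list(hr))
  }
  groups
}

.reprojRing <- function(ring, zone, north, inverse = FALSE) {
  if (inverse) lonLatToUTM(ring[, 1L], ring[, 2L], zone, north)
  else utmToLonLat(ring[, 1L], ring[, 2L], zone, north)
}

#' Write raft records as RFC 7946 GeoJSON
#'
#' Geometries are reprojected from the records' projected UTM CRS to
#' WGS84 longitude/latitude as the GeoJSON standard requires; the
#' projected CRS is kept as a foreign member \code{crs_projected} so
#' \code{\link{readGeoJSON}} can restore projected coordinates. Absent
#' distances serialize as null.
#'
#' @param records data.frame from \code{\link{buildRecords}}
#' @param path output file
#' @return the path, invisibly
#' @export
writeGeoJSON <- function(records, path) {
  crs <- attr(records, "crs")
  zn <- if (!is.null(crs) && nzchar(crs)) .epsgZone(crs) else NULL
  feats <- lapply(seq_len(nrow(records)), function(k) {
    rings <- records$geometry[[k]]
    groups <- .groupRings(rings)
    coordsOf <- function(g) {
      ringList <- c(list(g$outer), g$holes)
      lapply(ringList, function(rg) {
        ll <- if (is.null(zn)) rg else .reprojRing(rg, zn$zone, zn$north)
        lapply(seq_len(nrow(ll)), function(i) c(ll[i, 1L], ll[i, 2L]))
      })
    }
    geom <- if (length(groups) == 1L)
      list(type = "Polygon", coordinates = coordsOf(groups[[1L]]))
    else
      list(type = "MultiPolygon",
           coordinates = lapply(groups, coordsOf))
    d <- records$distance_to_coast_km[k]
    list(type = "Feature",
         geometry = geom,
         properties = list(
           id = records$id[k],
           acquisition_date = format(records$acquisition_date[k],
                                     "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
           tile_id = records$tile_id[k],
           pixel_count = records$pixel_count[k],
           area_km2 = records$area_km2[k],
           distance_to_coast_km = if (is.na(d)) NULL else d,
           distance_bin = if (is.na(records$distance_bin[k])) NULL
                          else records$distance_bin[k],
           location_class = records$location_class[k],
           edge_touching = records$edge_touching[k]))
  })
  obj <- list(type = "FeatureCollection",
              crs_projected = if (is.null(zn)) NULL else crs,
              features = feats)
  obj <- obj[!vapply(obj, is.null, TRUE)]
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10,
                           null = "null", na = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read raft records from GeoJSON written by \code{\link{writeGeoJSON}}
#'
#' @param path the GeoJSON file
#' @return data.frame with the attribute columns and a \code{geometry}
#'   list-column; coordinates are restored to the projected CRS when the
#'   file carries the \code{crs_projected} foreign member
#' @export
readGeoJSON <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("parse error in ", path, ": ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(obj$type) || obj$type != "FeatureCollection")
    stop("parse error: not a FeatureCollection", call. = FALSE)
  crs <- obj$crs_projected
  zn <- if (!is.null(crs)) .epsgZone(crs) else NULL
  feats <- obj$features
  getp <- function(f, nm) {
    v <- f$properties[[nm]]
    if (is.null(v)) NA else v
  }
  geoms <- lapply(feats, function(f) {
    g <- f$geometry
    polys <- if (g$type == "Polygon") list(g$coordinates) else g$coordinates
    rings <- list()
    for (p in polys) for (rg in p) {
      m <- do.call(rbind, lapply(rg, unlist))
      if (!is.null(zn))
        m <- .reprojRing(m, zn$zone, zn$north, inverse = TRUE)
      colnames(m) <- c("x", "y")
      rings <- c(rings, list(m))
    }
    rings
  })
  rec <- data.frame(
    id = vapply(feats, function(f) as.integer(getp(f, "id")), 0L),
    acquisition_date = as.POSIXct(
      vapply(feats, function(f) as.character(getp(f, "acquisition_date")), ""),
      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    tile_id = vapply(feats, function(f) as.character(getp(f, "tile_id")), ""),
    pixel_count = vapply(feats, function(f) as.integer(getp(f, "pixel_count")), 0L),
    area_km2 = vapply(feats, function(f) as.numeric(getp(f, "area_km2")), 0.0),
    distance_to_coast_km = vapply(feats, function(f)
      as.numeric(getp(f, "distance_to_coast_km")), 0.0),
    distance_bin = vapply(feats, function(f)
      as.character(getp(f, "distance_bin")), ""),
    location_class = vapply(feats, function(f)
      as.character(getp(f, "location_class")), ""),
    edge_touching = vapply(feats, function(f)
      as.logical(getp(f, "edge_touching")), TRUE),
    stringsAsFactors = FALSE)
  rec$geometry <- I(geoms)
  if (!is.null(crs)) attr(rec, "crs") <- crs
  rec
}

#' Export the attribute table as CSV
#'
#' Mirrors the portal's attribute table columns (no geometry).
#'
#' @param records data.frame from \code{\link{buildRecords}}
#' @param path output CSV
#' @return the path, invisibly
#' @export
recordsToCSV <- function(records, path) {
  df <- records[setdiff(names(records), "geometry")]
  df$acquisition_date <- format(df$acquisition_date, "%Y-%m-%dT%H:%M:%SZ",
                                tz = "UTC")
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
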