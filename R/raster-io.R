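## Georeferenced raster I/O.
##
## Rasters travel as TIFF pixel data plus an ESRI world file (.tfw) for
## the affine georeference and a small YAML sidecar (<path>.aux.yaml)
## carrying CRS, acquisition metadata and the value encoding. Because
## TIFF float storage is defined on [0, 1] here, continuous rasters are
## written with a fixed affine value encoding recorded in the sidecar:
## stored = (value - offset) / gain.

.ENCODINGS <- list(
  reflectance = list(offset = -0.1, gain = 1.6, bits = 32L),
  fai         = list(offset = -2.0, gain = 4.0, bits = 32L),
  mask8       = list(offset = 0.0,  gain = 255, bits = 8L),
  scl         = list(offset = 0.0,  gain = 255, bits = 8L)
)

.worldPath <- function(path) sub("\\.[^.]+$", ".tfw", path)
.sidecarPath <- function(path) paste0(path, ".aux.yaml")

.writeWorldFile <- function(path, transform) {
  ## world-file lines: dx, 0, 0, -dy, x of center of UL pixel, y of same
  lines <- formatC(c(transform[3L], 0, 0, -transform[4L],
                     transform[1L] + transform[3L] / 2,
                     transform[2L] - transform[4L] / 2),
                   format = "f", digits = 10)
  writeLines(lines, .worldPath(path))
}

.readWorldFile <- function(path) {
  wf <- as.numeric(readLines(.worldPath(path)))
  dx <- wf[1L]; dy <- -wf[4L]
  c(x0 = wf[5L] - dx / 2, y0 = wf[6L] + dy / 2, dx = dx, dy = dy)
}

#' Write a single-band georeferenced TIFF
#'
#' @param values numeric matrix
#' @param path output file (.tif); a .tfw world file and a .aux.yaml
#'   sidecar are written next to it
#' @param transform numeric(4) grid transform
#' @param crs CRS identifier
#' @param encoding one of \code{"reflectance"}, \code{"fai"},
#'   \code{"mask8"}, \code{"scl"} (fixed value scaling, see sidecar)
#' @param meta named list of extra sidecar entries
#' @return the path, invisibly
#' @export
writeRasterTIFF <- function(values, path, transform, crs = "",
                            encoding = "reflectance", meta = list()) {
  enc <- .ENCODINGS[[encoding]]
  if (is.null(enc)) stop("unknown encoding: ", encoding, call. = FALSE)
  stored <- (values - enc$offset) / enc$gain
  stored[!is.finite(stored)] <- 0
  stored <- pmin(pmax(stored, 0), 1)
  dim(stored) <- dim(values)
  tiff::writeTIFF(stored, path, bits.per.sample = enc$bits)
  .writeWorldFile(path, transform)
  sc <- c(list(crs = crs,
               transform = as.numeric(transform),
               encoding = list(kind = encoding, offset = enc$offset,
                               gain = enc$gain)),
          meta)
  yaml::write_yaml(sc, .sidecarPath(path))
  invisible(path)
}

#' Read a single-band georeferenced TIFF
#'
#' Reads pixel data, world-file georeference and sidecar metadata;
#' values are decoded with the sidecar's encoding when present. Integer
#' rasters without a sidecar are interpreted as digital numbers and
#' divided by \code{quantification}.
#'
#' @param path the .tif file
#' @param quantification DN divisor for sidecar-less integer rasters
#' @return list with \code{values}, \code{transform}, \code{crs},
#'   \code{meta}
#' @export
readRasterTIFF <- function(path, quantification = 10000) {
  if (!file.exists(path))
    stop("I/O error: cannot read ", path, call. = FALSE)
  scp <- .sidecarPath(path)
  if (file.exists(scp)) {
    sc <- yaml::read_yaml(scp)
    raw <- tiff::readTIFF(path)
    values <- raw * sc$encoding$gain + sc$encoding$offset
    transform <- as.numeric(sc$transform)
    crs <- sc$crs
    meta <- sc[setdiff(names(sc), c("transform", "crs", "encoding"))]
  } else {
    raw <- tiff::readTIFF(path, as.is = TRUE)
    values <- if (is.integer(raw) || max(raw) > 1.5)
      raw / quantification else raw
    dim(values) <- dim(raw)[1:2]
    transform <- if (file.exists(.worldPath(path)))
      .readWorldFile(path) else c(0, 0, 1, 1)
    crs <- ""
    meta <- list()
  }
  if (length(dim(values)) > 2L) values <- values[, , 1L]
  list(values = values, transform = transform, crs = crs, meta = meta)
}

## SAFE-style filename tokens: tile (T16QDJ) and datetime (20220715T160901)
.parseSceneName <- function(fname) {
  out <- list(tileId = NA_character_, datetime = NULL)
  m <- regmatches(fname, regexpr("T[0-9]{2}[C-X][A-Z]{2}", fname))
  if (length(m)) out$tileId <- m
  d <- regmatches(fname, regexpr("[0-9]{8}T[0-9]{6}", fname))
  if (length(d))
    out$datetime <- as.POSIXct(d, format = "%Y%m%dT%H%M%S", tz = "UTC")
  out
}

#' Assemble a Scene from single-band rasters
#'
#' @param paths named character vector mapping band ids (b04, b08, b8A,
#'   b11, ... or red, nir, swir) to raster files; all must share shape
#'   and georeference
#' @param datetime acquisition time; if NULL, parsed from the first
#'   filename's SAFE-style token
#' @param tileId MGRS id; if NULL, parsed from the first filename
#' @param sensor \code{"S2"} or \code{"L8"}
#' @param quantification DN divisor for integer rasters (default 10000)
#' @param nodataValue reflectance value flagged as nodata in the files
#'   (default: none)
#' @return a validated \code{\linkS4class{Scene}}
#' @export
readScene <- function(paths, datetime = NULL, tileId = NULL, sensor = "S2",
                      quantification = 10000, nodataValue = NULL) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("configuration error: paths must be named by band id", call. = FALSE)
  rs <- lapply(paths, readRasterTIFF, quantification = quantification)
  dims <- unique(lapply(rs, function(r) dim(r$values)))
  if (length(dims) > 1L)
    stop("geometry error: band rasters differ in shape", call. = FALSE)
  trs <- unique(lapply(rs, function(r) round(unname(r$transform), 6)))
  if (length(trs) > 1L)
    stop("geometry error: band rasters differ in georeference", call. = FALSE)
  crss <- setdiff(unique(vapply(rs, function(r) r$crs, "")), "")
  if (length(crss) > 1L)
    stop("geometry error: band rasters differ in CRS", call. = FALSE)
  bands <- lapply(rs, `[[`, "values")
  nodata <- Reduce(`|`, lapply(bands, function(b) !is.finite(b)))
  if (!is.null(nodataValue))
    nodata <- nodata | Reduce(`|`, lapply(bands, function(b) b == nodataValue))
  ## metadata precedence: explicit argument > sidecar > filename tokens
  parsed <- .parseSceneName(basename(paths[[1L]]))
  meta1 <- rs[[1L]]$meta
  if (is.null(tileId))
    tileId <- if (!is.null(meta1$tile_id)) meta1$tile_id else parsed$tileId
  if (is.null(datetime)) {
    datetime <- if (!is.null(meta1$datetime))
      as.POSIXct(meta1$datetime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    else parsed$datetime
  }
  if (is.null(datetime) || is.na(tileId))
    stop("configuration error: acquisition datetime and tile id are required ",
         "(pass them or encode them in the filename)", call. = FALSE)
  Scene(bands, transform = trs[[1L]],
        crs = if (length(crss)) crss else "",
        datetime = datetime, tileId = tileId, sensor = sensor,
        nodata = nodata)
}

#' Write a detection mask as an 8-bit georeferenced TIFF
#'
#' Coding: 1 = Sargassum, 0 = background, 255 = nodata. Nodata wins over
#' detection (a nodata pixel is written 255 even if the mask were true
#' there).
#'
#' @param mask a \code{\linkS4class{DetectionMask}}
#' @param scene the source \code{\linkS4class{Scene}} (georeference and
#'   nodata)
#' @param path output .tif
#' @return the path, invisibly
#' @export
writeMask <- function(mask, scene, path) {
  if (!identical(dim(mask@values), dim(scene)))
    stop("geometry error: mask and scene shapes differ", call. = FALSE)
  v <- matrix(0, nrow(mask@values), ncol(mask@values))
  v[mask@values] <- 1
  v[scene@nodata] <- 255
  writeRasterTIFF(v, path, scene@transform, scene@crs, encoding = "mask8",
                  meta = list(
                    datetime = format(scene@datetime, "%Y-%m-%dT%H:%M:%SZ",
                                      tz = "UTC"),
                    tile_id = scene@tileId,
                    stages = as.list(mask@stages)))
}

#' Read back a detection mask written by \code{\link{writeMask}}
#'
#' @param path the .tif file
#' @return list with logical \code{values}, logical \code{nodata},
#'   \code{transform}, \code{crs}, \code{meta}
#' @export
readMask <- function(path) {
  r <- readRasterTIFF(path)
  codes <- round(r$values)
  list(values = codes == 1, nodata = codes == 255,
       transform = r$transform, crs = r$crs, meta = r$meta)
}

#' Render an 8-bit RGB composite
#'
#' True color uses (b04, b03, b02); false color (b8A, b05, b04), in
#' which floating vegetation lights up in the red channel against dark
#' water. Each channel is stretched linearly between the given
#' percentiles of its valid pixels and clipped to 0..255; a degenerate
#' stretch (equal percentile values) renders mid-gray 127. Nodata pixels
#' render black.
#'
#' @param scene a \code{\linkS4class{Scene}}
#' @param mode \code{"true_color"} or \code{"false_color"}
#' @param stretch percentile pair, default \code{c(2, 98)}
#' @param path optional PNG output path
#' @return integer array (nrow, ncol, 3) of 0..255, invisibly when
#'   \code{path} is given
#' @export
renderComposite <- function(scene, mode = c("false_color", "true_color"),
                            stretch = c(2, 98), path = NULL) {
  mode <- match.arg(mode)
  want <- if (mode == "true_color") c("b04", "b03", "b02")
          else c("b8A", "b05", "b04")
  missing <- setdiff(want, names(sceneBands(scene)))
  if (length(missing))
    stop("configuration error: composite needs band(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  ok <- !scene@nodata
  out <- array(0L, c(nrow(scene@nodata), ncol(scene@nodata), 3L))
  for (k in 1:3) {
    b <- sceneBand(scene, want[k])
    qs <- stats::quantile(b[ok], probs = stretch / 100, names = FALSE,
                          type = 7)
    if (qs[2L] > qs[1L]) {
      ch <- round((b - qs[1L]) / (qs[2L] - qs[1L]) * 255)
      ch <- pmin(pmax(ch, 0), 255)
    } else {
      ch <- matrix(127, nrow(b), ncol(b))
    }
    ch[!ok] <- 0
    out[, , k] <- as.integer(ch)
  }
  if (!is.null(path)) {
    png::writePNG(out / 255, path)
    return(invisible(out))
  }
  out
}
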