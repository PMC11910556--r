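## Grid geometry and UTM <-> geographic conversion.
##
## The affine convention is fixed package-wide: transform = c(x0, y0, dx, dy)
## with (x0, y0) the projected coordinate of the upper-left corner of pixel
## (1, 1); x = x0 + col*dx grows with column, y = y0 - row*dy shrinks with
## row (north-up grid, dx, dy > 0).

#' Pixel-center projected coordinates
#'
#' @param transform numeric(4) \code{c(x0, y0, dx, dy)}
#' @param row,col 1-based pixel indices (vectors of equal length)
#' @return two-column matrix of (x, y) centers, meters
#' @export
pixelCenter <- function(transform, row, col) {
  cbind(x = transform[1L] + (col - 0.5) * transform[3L],
        y = transform[2L] - (row - 0.5) * transform[4L])
}

## Pixel-corner coordinate: corner grid node (r, c), r in 0..nrow, c in 0..ncol
.cornerXY <- function(transform, r, c) {
  cbind(transform[1L] + c * transform[3L], transform[2L] - r * transform[4L])
}

## ---- Transverse Mercator (WGS84), Krueger series to n^4 ----

.WGS84_A <- 6378137
.WGS84_F <- 1 / 298.257223563

.tmConsts <- local({
  f <- 1 / 298.257223563
  n <- f / (2 - f)
  list(
    n = n,
    e = sqrt(f * (2 - f)),
    A = 6378137 / (1 + n) * (1 + n^2 / 4 + n^4 / 64),
    alpha = c(n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180,
              13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440,
              61 * n^3 / 240 - 103 * n^4 / 140,
              49561 * n^4 / 161280),
    beta = c(n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360,
             n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440,
             17 * n^3 / 480 - 37 * n^4 / 840,
             4397 * n^4 / 161280),
    delta = c(2 * n - 2 * n^2 / 3 - 2 * n^3 + 116 * n^4 / 45,
              7 * n^2 / 3 - 8 * n^3 / 5 - 227 * n^4 / 45,
              56 * n^3 / 15 - 136 * n^4 / 35,
              4279 * n^4 / 630))
})

#' Geographic to UTM (WGS84)
#'
#' Transverse Mercator with the standard UTM constants (k0 = 0.9996,
#' false easting 500 km, false northing 10000 km in the south), using a
#' fourth-order series in the third flattening (sub-millimeter over a
#' UTM zone).
#'
#' @param lon,lat degrees (vectors)
#' @param zone UTM zone number 1..60
#' @param north TRUE for the northern hemisphere
#' @return two-column matrix of (x, y) = (easting, northing), meters
#' @export
lonLatToUTM <- function(lon, lat, zone, north = TRUE) {
  k <- .tmConsts
  lam0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  dlam <- lon * pi / 180 - lam0
  s <- sin(phi)
  t <- sinh(atanh(s) - k$e * atanh(k$e * s))
  xi <- atan2(t, cos(dlam))
  eta <- atanh(sin(dlam) / sqrt(1 + t^2))
  xi0 <- xi; eta0 <- eta
  for (j in 1:4) {
    xi  <- xi  + k$alpha[j] * sin(2 * j * xi0) * cosh(2 * j * eta0)
    eta <- eta + k$alpha[j] * cos(2 * j * xi0) * sinh(2 * j * eta0)
  }
  x <- 500000 + 0.9996 * k$A * eta
  y <- 0.9996 * k$A * xi + if (north) 0 else 1e7
  cbind(x = x, y = y)
}

#' UTM to geographic (WGS84)
#'
#' Inverse of \code{\link{lonLatToUTM}}.
#'
#' @param x,y easting and northing, meters (vectors)
#' @param zone UTM zone number 1..60
#' @param north TRUE for the northern hemisphere
#' @return two-column matrix of (lon, lat), degrees
#' @export
utmToLonLat <- function(x, y, zone, north = TRUE) {
  k <- .tmConsts
  lam0 <- (zone * 6 - 183) * pi / 180
  xi <- (y - if (north) 0 else 1e7) / (0.9996 * k$A)
  eta <- (x - 500000) / (0.9996 * k$A)
  xi0 <- xi; eta0 <- eta
  for (j in 1:4) {
    xi  <- xi  - k$beta[j] * sin(2 * j * xi0) * cosh(2 * j * eta0)
    eta <- eta - k$beta[j] * cos(2 * j * xi0) * sinh(2 * j * eta0)
  }
  chi <- asin(sin(xi) / cosh(eta))
  phi <- chi
  for (j in 1:4) phi <- phi + k$delta[j] * sin(2 * j * chi)
  lam <- lam0 + atan2(sinh(eta), cos(xi))
  cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
}

#' UTM zone and hemisphere of an MGRS granule id
#'
#' @param tile MGRS identifier such as \code{"T16QDJ"}
#' @return list with \code{zone} (integer), \code{north} (logical) and
#'   \code{epsg} (e.g. \code{"EPSG:32616"})
#' @export
mgrsZone <- function(tile) {
  if (!grepl("^T[0-9]{2}[C-X][A-Z]{2}$", tile))
    stop("malformed MGRS tile id: ", tile, call. = FALSE)
  zone <- as.integer(substr(tile, 2L, 3L))
  band <- substr(tile, 4L, 4L)
  north <- band >= "N"
  list(zone = zone, north = north,
       epsg = sprintf("EPSG:%d", if (north) 32600L + zone else 32700L + zone))
}

.epsgZone <- function(crs) {
  m <- regmatches(crs, regexec("^EPSG:32([67])([0-9]{2})$", crs))[[1L]]
  if (length(m) != 3L)
    stop("unsupported CRS for reprojection: ", crs,
         " (expected a UTM/WGS84 EPSG code)", call. = FALSE)
  list(zone = as.integer(m[3L]), north = m[2L] == "6")
}
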