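# Independent brute-force oracles. Everything here is deliberately
# naive (per-pixel loops, dense sampling) and shares no code with the
# package implementations it checks.

# per-pixel evaluation of the five-condition detection rule
bruteEq1 <- function(b04, b08, b8A, b11, nodata = NULL,
                     t8A = 0.07, t04 = 0.10, t11 = 0.05) {
  nr <- nrow(b04); nc <- ncol(b04)
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!is.null(nodata) && nodata[i, j]) next
    out[i, j] <- (b8A[i, j] < t8A) && (b04[i, j] < t04) &&
      (b11[i, j] < t11) && (b04[i, j] < b8A[i, j]) && (b04[i, j] < b08[i, j])
  }
  out
}

# stack-based flood fill labeling, row-major component numbering
bruteLabel <- function(values, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  nb <- if (connectivity == 4) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
        else list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                  c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  cur <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!values[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j)); lab[i, j] <- cur
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in nb) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
            values[q[1], q[2]] && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          stack[[length(stack) + 1L]] <- q
        }
      }
    }
  }
  lab
}

# windowed-histogram Shannon entropy, loops over every pixel;
# rng = NULL quantizes over the valid min-max instead of a fixed interval
bruteEntropy <- function(band, nodata, w, Q, rng = c(0, 1)) {
  nr <- nrow(band); nc <- ncol(band)
  valid <- !nodata
  if (is.null(rng)) rng <- range(band[valid])
  lev <- if (rng[2] > rng[1])
    pmin(pmax(floor((band - rng[1]) / (rng[2] - rng[1]) * Q), 0), Q - 1) else
    matrix(0, nr, nc)
  h <- (w - 1) / 2
  H <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- max(1, i - h):min(nr, i + h)
    jj <- max(1, j - h):min(nc, j + h)
    vals <- lev[ii, jj][valid[ii, jj]]
    if (!length(vals)) next
    p <- table(vals) / length(vals)
    H[i, j] <- -sum(p * log2(p))
  }
  H
}

# dense boundary sampling + exact point-to-segment distance, refined
# locally around the coarse minimum
bruteMinDist <- function(rings, lines, coarse = 0.05, fine = 1e-4) {
  segs <- do.call(rbind, lapply(lines, function(l)
    cbind(l[-nrow(l), , drop = FALSE], l[-1, , drop = FALSE])))
  pdist <- function(px, py) {
    best <- rep(Inf, length(px))
    for (s in seq_len(nrow(segs))) {
      ax <- segs[s, 1]; ay <- segs[s, 2]; bx <- segs[s, 3]; by <- segs[s, 4]
      vx <- bx - ax; vy <- by - ay; l2 <- vx^2 + vy^2
      t <- if (l2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / l2))
      best <- pmin(best, sqrt((px - ax - t * vx)^2 + (py - ay - t * vy)^2))
    }
    best
  }
  sampleEdge <- function(a, b, step) {
    len <- sqrt(sum((b - a)^2))
    t <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  best <- Inf; bestA <- NULL; bestB <- NULL
  for (ring in rings) {
    for (k in seq_len(nrow(ring) - 1)) {
      pts <- sampleEdge(ring[k, ], ring[k + 1, ], coarse)
      d <- pdist(pts[, 1], pts[, 2])
      m <- which.min(d)
      if (d[m] < best) { best <- d[m]; bestA <- ring[k, ]; bestB <- ring[k + 1, ]
        bestP <- pts[m, ] }
    }
  }
  # refine around the best boundary point
  dirv <- bestB - bestA
  len <- sqrt(sum(dirv^2)); u <- dirv / len
  t0 <- sum((bestP - bestA) * u)
  tt <- seq(max(0, t0 - 2 * coarse), min(len, t0 + 2 * coarse), by = fine)
  px <- bestA[1] + tt * u[1]; py <- bestA[2] + tt * u[2]
  min(best, min(pdist(px, py)))
}

# naive predicate scan for record queries
bruteQuery <- function(records, areaOp = NULL, areaKm2 = NULL,
                       from = NULL, to = NULL, locationClass = NULL) {
  keep <- logical(nrow(records))
  for (k in seq_len(nrow(records))) {
    ok <- TRUE
    if (!is.null(areaOp)) {
      a <- records$area_km2[k]
      ok <- ok && switch(areaOp, ge = a >= areaKm2, le = a <= areaKm2,
                         eq = abs(a - areaKm2) <= 1e-9)
    }
    if (!is.null(from)) ok <- ok && records$acquisition_date[k] >= from
    if (!is.null(to)) ok <- ok && records$acquisition_date[k] <= to
    if (!is.null(locationClass))
      ok <- ok && records$location_class[k] == locationClass
    keep[k] <- ok
  }
  records[keep, , drop = FALSE]
}

# Snyder-series transverse Mercator forward projection (independent of
# the package's Krueger-series implementation)
snyderUTM <- function(lon, lat, zone, north = TRUE) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  phi <- lat * pi / 180
  lam <- lon * pi / 180; lam0 <- (zone * 6 - 183) * pi / 180
  N <- a / sqrt(1 - e2 * sin(phi)^2)
  T <- tan(phi)^2; C <- ep2 * cos(phi)^2
  A <- cos(phi) * (lam - lam0)
  M <- a * ((1 - e2 / 4 - 3 * e2^2 / 64 - 5 * e2^3 / 256) * phi -
            (3 * e2 / 8 + 3 * e2^2 / 32 + 45 * e2^3 / 1024) * sin(2 * phi) +
            (15 * e2^2 / 256 + 45 * e2^3 / 1024) * sin(4 * phi) -
            (35 * e2^3 / 3072) * sin(6 * phi))
  x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                 (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 500000
  y <- k0 * (M + N * tan(phi) * (A^2 / 2 +
             (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
             (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720))
  if (!north) y <- y + 1e7
  c(x = x, y = y)
}

# meridian arc length by direct numerical integration of the meridian
# radius of curvature
meridianArc <- function(lat) {
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  integrate(function(p) a * (1 - e2) / (1 - e2 * sin(p)^2)^1.5,
            0, lat * pi / 180, rel.tol = 1e-13)$value
}

# minimal Scene on a pixelSize grid, constant bands
toyScene <- function(nr, nc, pixelSize = 20, bands = NULL, nodata = NULL,
                     tile = "T16QDJ") {
  if (is.null(bands))
    bands <- list(b04 = matrix(0.03, nr, nc), b08 = matrix(0.02, nr, nc),
                  b8A = matrix(0.015, nr, nc), b11 = matrix(0.005, nr, nc))
  Scene(bands, transform = c(3e5, 2.1e6, pixelSize, pixelSize),
        crs = "EPSG:32616", datetime = "2022-07-15 16:09:01",
        tileId = tile, sensor = "S2", nodata = nodata)
}

randomMask <- function(nr, nc, p = 0.4) matrix(runif(nr * nc) < p, nr, nc)

# synthetic raft-record table with the full attribute schema
.fakeRecords <- function(areas, dates = NULL, classes = NULL) {
  n <- length(areas)
  if (is.null(dates))
    dates <- as.POSIXct("2022-07-01", tz = "UTC") + seq_len(n) * 86400
  if (is.null(classes)) classes <- rep("ocean", n)
  data.frame(id = seq_len(n), acquisition_date = dates,
             tile_id = rep("T16QDJ", n),
             pixel_count = as.integer(areas * 1e6 / 400),
             area_km2 = as.numeric(areas),
             distance_to_coast_km = rep(NA_real_, n),
             distance_bin = rep(NA_character_, n), location_class = classes,
             edge_touching = rep(FALSE, n), stringsAsFactors = FALSE)
}
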