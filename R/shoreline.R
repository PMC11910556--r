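## Shoreline derivation and persistent sandy-beach masks.

#' Derive shoreline polylines from a land/water grid
#'
#' The shoreline is the set of pixel-boundary edges between 4-adjacent
#' land/water pixel pairs, chained into polylines (closed rings for
#' islands/lakes, open chains where the boundary meets the grid edge).
#'
#' @param landWater logical matrix, TRUE = land
#' @param transform numeric(4) grid transform
#' @param crs CRS identifier
#' @return a \code{\linkS4class{Coastline}} in projected meters
#' @export
deriveShoreline <- function(landWater, transform = c(0, 0, 1, 1), crs = "") {
  if (all(landWater) || !any(landWater))
    stop("degenerate input: grid must contain both land and water",
         call. = FALSE)
  nr <- nrow(landWater); nc <- ncol(landWater)
  ## horizontal boundary edges (between vertically adjacent pixels):
  ## land(i,j) vs water(i+1,j) or vice versa -> edge along r = i
  vdiff <- landWater[-nr, , drop = FALSE] != landWater[-1L, , drop = FALSE]
  hdiff <- landWater[, -nc, drop = FALSE] != landWater[, -1L, drop = FALSE]
  segs <- list()
  wh <- which(vdiff, arr.ind = TRUE)
  if (nrow(wh))
    segs <- c(segs, lapply(seq_len(nrow(wh)), function(k)
      rbind(c(wh[k, 1L], wh[k, 2L] - 1L), c(wh[k, 1L], wh[k, 2L]))))
  wv <- which(hdiff, arr.ind = TRUE)
  if (nrow(wv))
    segs <- c(segs, lapply(seq_len(nrow(wv)), function(k)
      rbind(c(wv[k, 1L] - 1L, wv[k, 2L]), c(wv[k, 1L], wv[k, 2L]))))
  ## chain undirected unit edges (corner-grid nodes) into polylines
  vkey <- function(rc) rc[, 1L] * (nc + 1L) + rc[, 2L] + 1L
  ends <- do.call(rbind, segs)
  a <- vkey(ends[seq(1L, nrow(ends), 2L), , drop = FALSE])
  b <- vkey(ends[seq(2L, nrow(ends), 2L), , drop = FALSE])
  adj <- new.env(hash = TRUE)
  addE <- function(u, v, e) {
    key <- as.character(u)
    adj[[key]] <- rbind(adj[[key]], c(v, e))
  }
  for (e in seq_along(a)) { addE(a[e], b[e], e); addE(b[e], a[e], e) }
  used <- logical(length(a))
  deg <- table(c(a, b))
  chains <- list()
  walk <- function(start) {
    path <- start
    cur <- start
    repeat {
      nbrs <- adj[[as.character(cur)]]
      nxt <- nbrs[!used[nbrs[, 2L]], , drop = FALSE]
      if (nrow(nxt) == 0L) break
      used[nxt[1L, 2L]] <<- TRUE
      cur <- nxt[1L, 1L]
      path <- c(path, cur)
    }
    path
  }
  ## open chains first (start at odd-degree nodes), then remaining cycles
  oddNodes <- as.numeric(names(deg)[deg %% 2 == 1])
  for (s in oddNodes) {
    repeat {
      nbrs <- adj[[as.character(s)]]
      if (is.null(nbrs) || all(used[nbrs[, 2L]])) break
      chains[[length(chains) + 1L]] <- walk(s)
    }
  }
  while (any(!used)) {
    e <- which(!used)[1L]
    used[e] <- TRUE
    p <- walk(b[e])
    chains[[length(chains) + 1L]] <- c(a[e], p)
  }
  lines <- lapply(chains, function(vs) {
    r <- (vs - 1L) %/% (nc + 1L)
    c0 <- (vs - 1L) %% (nc + 1L)
    cbind(x = transform[1L] + c0 * transform[3L],
          y = transform[2L] - r * transform[4L])
  })
  Coastline(lines, crs = crs)
}

## distance from pixel centers to the nearest coastline segment
.centersWithin <- function(dims, transform, coastline, maxDistM) {
  nr <- dims[1L]; nc <- dims[2L]
  ctr <- pixelCenter(transform, rep(seq_len(nr), times = nc),
                     rep(seq_len(nc), each = nr))
  best <- rep(Inf, nrow(ctr))
  for (line in coastline@lines) {
    for (s in seq_len(nrow(line) - 1L)) {
      d <- .pointSegDist(ctr[, 1L], ctr[, 2L],
                         line[s, 1L], line[s, 2L],
                         line[s + 1L, 1L], line[s + 1L, 2L])
      best <- pmin(best, d)
    }
  }
  matrix(best <= maxDistM, nr, nc)
}

#' Derive the persistent sandy-beach mask
#'
#' A pixel is sandy beach iff its cover code is \code{bare} in every
#' epoch of the stack (never vegetation, water or nodata -- "devoid of
#' vegetation" across dry and rainy seasons) and its center lies within
#' \code{maxShoreDistanceM} of the shoreline. When \code{seasonal} is
#' TRUE the stack must contain at least one dry- and one rainy-season
#' epoch; otherwise all epochs are treated equally.
#'
#' @param stack a \code{\linkS4class{CoverStack}}
#' @param shoreline a \code{\linkS4class{Coastline}}
#' @param maxShoreDistanceM shoreline buffer width, meters (default 100)
#' @param seasonal require dry + rainy epoch labels (default FALSE)
#' @return a \code{\linkS4class{BeachMask}}
#' @export
deriveBeachMask <- function(stack, shoreline, maxShoreDistanceM = 100,
                            seasonal = FALSE) {
  if (!is(shoreline, "Coastline") || length(shoreline@lines) == 0L)
    stop("contract violation: a non-empty shoreline is required",
         call. = FALSE)
  if (seasonal &&
      !(all(c("dry", "rainy") %in% stack@seasons)))
    stop("seasonal mode requires at least one dry and one rainy epoch",
         call. = FALSE)
  bare <- Reduce(`&`, lapply(stack@epochs, function(e) e == 3L))
  near <- .centersWithin(dim(stack@epochs[[1L]]), stack@transform,
                         shoreline, maxShoreDistanceM)
  new("BeachMask", values = bare & near,
      maxShoreDistanceM = maxShoreDistanceM,
      transform = stack@transform, crs = stack@crs)
}

#' NDVI-based cover classification helper
#'
#' Optional helper to derive cover codes from red/NIR reflectance when
#' no external classification is available: water where NIR is very dark
#' and NDVI negative, vegetation where NDVI exceeds the vegetation
#' threshold, bare otherwise. The thresholds are configurable; this is a
#' deliberately simple rule, not a full land-cover classifier.
#'
#' @param red,nir reflectance matrices
#' @param ndviBare NDVI below which (and above water) a pixel is bare
#'   (default 0.2)
#' @param waterNIR NIR reflectance below which a negative-NDVI pixel is
#'   water (default 0.05)
#' @param nodata optional logical matrix
#' @return integer cover-code matrix (0 nodata, 1 water, 2 vegetation,
#'   3 bare)
#' @export
coverFromNDVI <- function(red, nir, ndviBare = 0.2, waterNIR = 0.05,
                          nodata = NULL) {
  ndvi <- (nir - red) / pmax(nir + red, 1e-9)
  code <- matrix(3L, nrow(red), ncol(red))
  code[ndvi >= ndviBare] <- 2L
  code[ndvi < 0 & nir < waterNIR] <- 1L
  if (!is.null(nodata)) code[nodata] <- 0L
  code
}
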