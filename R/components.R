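## Raster geometry engine: connected-component labeling, pixel-edge
## boundary tracing, even-odd rasterization, and planar distances.
## All pixel indices are 1-based; pixel (i, j) occupies the unit square
## with corners (r, c) in [i-1, i] x [j-1, j] of the corner grid.

#' Label connected components of a logical grid
#'
#' Components are numbered 1..n in row-major order of each component's
#' first pixel (scan rows top to bottom, columns left to right).
#'
#' @param values logical matrix
#' @param connectivity 4 or 8
#' @return integer matrix of labels, 0 = background
#' @export
labelComponents <- function(values, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(values); nc <- ncol(values)
  lab <- matrix(0L, nr, nc)
  if (!any(values)) return(lab)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  true_idx <- which(values)                       # column-major linear
  ti <- (true_idx - 1L) %% nr + 1L
  tj <- (true_idx - 1L) %/% nr + 1L
  seeds <- true_idx[order((ti - 1L) * nc + tj)]   # row-major scan order
  cur <- 0L
  for (s in seeds) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      fi <- (frontier - 1L) %% nr + 1L
      fj <- (frontier - 1L) %/% nr + 1L
      ni <- rep(fi, times = length(dr)) + rep(dr, each = length(fi))
      nj <- rep(fj, times = length(dc)) + rep(dc, each = length(fj))
      ok <- ni >= 1L & ni <= nr & nj >= 1L & nj <= nc
      nidx <- (nj[ok] - 1L) * nr + ni[ok]
      nidx <- unique(nidx[values[nidx] & lab[nidx] == 0L])
      lab[nidx] <- cur
      frontier <- nidx
    }
  }
  lab
}

## Trace the boundary rings of one component given its pixel linear
## indices (column-major) on an nr x nc grid. Returns a list of closed
## rings in corner coordinates (r, c) (matrix, first row repeated last).
## Directed edges keep the component interior on the RIGHT of travel in
## screen coordinates (r down); after the y-flip to projected space the
## outer rings come out counterclockwise (positive shoelace).
.traceRings <- function(pix, nr, nc, connectivity) {
  inside <- logical(nr * nc)
  inside[pix] <- TRUE
  i <- (pix - 1L) %% nr + 1L
  j <- (pix - 1L) %/% nr + 1L
  has <- function(ii, jj) {
    ok <- ii >= 1L & ii <= nr & jj >= 1L & jj <= nc
    idx <- (pmax(jj, 1L) - 1L) * nr + pmax(ii, 1L)
    ok & inside[idx]
  }
  ## directions: 0 = +c, 1 = +r, 2 = -c, 3 = -r
  ## per pixel: exposed top    -> edge (i-1, j-1) -> (i-1, j), dir 0
  ##            exposed right  -> edge (i-1, j)   -> (i,   j), dir 1
  ##            exposed bottom -> edge (i,   j)   -> (i,  j-1), dir 2
  ##            exposed left   -> edge (i,  j-1)  -> (i-1, j-1), dir 3
  vkey <- function(r, c) r * (nc + 1L) + c + 1L
  er <- integer(0); ec <- integer(0); dir <- integer(0)
  top <- !has(i - 1L, j)
  er <- c(er, (i - 1L)[top]); ec <- c(ec, (j - 1L)[top])
  dir <- c(dir, rep(0L, sum(top)))
  rgt <- !has(i, j + 1L)
  er <- c(er, (i - 1L)[rgt]); ec <- c(ec, j[rgt])
  dir <- c(dir, rep(1L, sum(rgt)))
  bot <- !has(i + 1L, j)
  er <- c(er, i[bot]); ec <- c(ec, j[bot])
  dir <- c(dir, rep(2L, sum(bot)))
  lft <- !has(i, j - 1L)
  er <- c(er, i[lft]); ec <- c(ec, (j - 1L)[lft])
  dir <- c(dir, rep(3L, sum(lft)))
  n <- length(er)
  if (n == 0L) return(list())
  ## from-vertex of each directed edge
  fromv <- vkey(er, ec)
  tor <- er + c(0L, 1L, 0L, -1L)[dir + 1L]
  toc <- ec + c(1L, 0L, -1L, 0L)[dir + 1L]
  tov <- vkey(tor, toc)
  ## outgoing edge lookup: vertices have 1 or 2 outgoing edges
  ord <- order(fromv)
  out1 <- new.env(hash = TRUE, size = n)
  for (e in seq_len(n)) {
    key <- as.character(fromv[e])
    out1[[key]] <- c(out1[[key]], e)
  }
  prefTurn <- if (connectivity == 8) 3L else 1L  # left turn : right turn
  used <- logical(n)
  rings <- list()
  for (start in seq_len(n)) {
    if (used[start]) next
    verts_r <- integer(0); verts_c <- integer(0)
    e <- start
    repeat {
      used[e] <- TRUE
      verts_r <- c(verts_r, er[e]); verts_c <- c(verts_c, ec[e])
      cand <- out1[[as.character(tov[e])]]
      cand <- cand[cand != e]
      if (length(cand) > 1L) {
        want <- (dir[e] + prefTurn) %% 4L
        pick <- cand[dir[cand] == want]
        e2 <- if (length(pick)) pick[1L] else cand[1L]
      } else e2 <- cand[1L]
      e <- e2
      if (e == start) break
    }
    ## reverse so outer rings are counterclockwise (positive shoelace)
    ## after the row-axis flip into projected coordinates
    ring <- cbind(r = c(verts_r, verts_r[1L]), c = c(verts_c, verts_c[1L]))
    ring <- ring[nrow(ring):1L, , drop = FALSE]
    rings[[length(rings) + 1L]] <- .mergeCollinear(ring)
  }
  rings
}

## drop interior vertices of straight runs; ring closed (first == last)
.mergeCollinear <- function(ring) {
  n <- nrow(ring) - 1L
  if (n < 4L) return(ring)
  v <- ring[seq_len(n), , drop = FALSE]
  prv <- v[c(n, seq_len(n - 1L)), , drop = FALSE]
  nxt <- v[c(seq_len(n - 1L) + 1L, 1L), , drop = FALSE]
  keep <- !((v[, 1L] - prv[, 1L]) * (nxt[, 2L] - v[, 2L]) ==
            (v[, 2L] - prv[, 2L]) * (nxt[, 1L] - v[, 1L]))
  v <- v[keep, , drop = FALSE]
  rbind(v, v[1L, , drop = FALSE])
}

## shoelace signed area of a closed ring (matrix, first == last row)
.ringSignedArea <- function(xy) {
  x <- xy[, 1L]; y <- xy[, 2L]
  n <- length(x)
  sum(x[-n] * y[-1L] - x[-1L] * y[-n]) / 2
}

## even-odd point-in-ring(s) test; rings in (x, y); points m x 2
.pointInRings <- function(pts, rings) {
  inside <- rep(FALSE, nrow(pts))
  for (ring in rings) {
    x1 <- ring[-nrow(ring), 1L]; y1 <- ring[-nrow(ring), 2L]
    x2 <- ring[-1L, 1L]; y2 <- ring[-1L, 2L]
    for (k in seq_len(nrow(pts))) {
      px <- pts[k, 1L]; py <- pts[k, 2L]
      cross <- ((y1 > py) != (y2 > py)) &
        (px < x1 + (py - y1) * (x2 - x1) / (y2 - y1))
      inside[k] <- xor(inside[k], sum(cross, na.rm = TRUE) %% 2 == 1)
    }
  }
  inside
}

#' Rasterize pixel-edge polygons back onto a grid
#'
#' Inverse of \code{\link{maskToPolygons}} for polygons whose boundaries
#' run along pixel edges: a pixel is set when its center is inside the
#' rings under the even-odd rule.
#'
#' @param rings a list of closed rings (n-by-2 matrices of projected x,
#'   y), or a list of components each with a \code{rings} element
#' @param dims grid dimension \code{c(nrow, ncol)}
#' @param transform numeric(4) grid transform
#' @return logical matrix
#' @export
rasterizePolygons <- function(rings, dims, transform) {
  if (length(rings) && is.list(rings[[1L]]) && !is.matrix(rings[[1L]])) {
    rings <- unlist(lapply(rings, function(el)
      if (!is.null(el$rings)) el$rings else el), recursive = FALSE)
  }
  nr <- dims[1L]; nc <- dims[2L]
  tog <- matrix(0L, nr, nc)
  for (ring in rings) {
    ## projected -> corner coordinates
    cc <- (ring[, 1L] - transform[1L]) / transform[3L]
    rr <- (transform[2L] - ring[, 2L]) / transform[4L]
    n <- length(cc)
    for (k in seq_len(n - 1L)) {
      if (cc[k] == cc[k + 1L]) {            # vertical edge in pixel space
        c0 <- round(cc[k])
        r1 <- min(rr[k], rr[k + 1L]); r2 <- max(rr[k], rr[k + 1L])
        i1 <- floor(r1 + 0.5) + 1L; i2 <- ceiling(r2 - 0.5)
        jmax <- min(floor(c0 + 0.5), nc)
        if (jmax >= 1L && i2 >= i1) {
          i1 <- max(i1, 1L); i2 <- min(i2, nr)
          if (i2 >= i1) tog[i1:i2, jmax] <- tog[i1:i2, jmax] + 1L
        }
      }
    }
  }
  ## parity of toggles at columns >= j
  suffix <- t(apply(tog[, nc:1, drop = FALSE], 1L, cumsum))[, nc:1, drop = FALSE]
  matrix(suffix %% 2L == 1L, nr, nc)
}

## min distance from points (m x 2) to one segment (a, b); vectorized
.pointSegDist <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  l2 <- vx * vx + vy * vy
  ## degenerate (point) segments have vx = vy = 0, so t is immaterial
  t <- pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / pmax(l2, 1e-300)))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

## do segments (p1,p2) and (q1,q2) intersect (including touching)?
.segIntersects <- function(p1, p2, q1, q2) {
  o <- function(a, b, c)
    sign((b[1L] - a[1L]) * (c[2L] - a[2L]) - (b[2L] - a[2L]) * (c[1L] - a[1L]))
  onseg <- function(a, b, c)
    min(a[1L], b[1L]) <= c[1L] && c[1L] <= max(a[1L], b[1L]) &&
    min(a[2L], b[2L]) <= c[2L] && c[2L] <= max(a[2L], b[2L])
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && onseg(p1, p2, q1)) || (o2 == 0 && onseg(p1, p2, q2)) ||
    (o3 == 0 && onseg(q1, q2, p1)) || (o4 == 0 && onseg(q1, q2, p2))
}

## min distance between a set of closed rings and a set of polylines; 0
## when they touch/cross or a polyline vertex lies inside the rings
.ringsToLinesDist <- function(rings, lines) {
  best <- Inf
  ## polyline vertex inside polygon?
  allv <- do.call(rbind, lines)
  if (any(.pointInRings(allv, rings))) return(0)
  for (ring in rings) {
    rx1 <- ring[-nrow(ring), 1L]; ry1 <- ring[-nrow(ring), 2L]
    rx2 <- ring[-1L, 1L]; ry2 <- ring[-1L, 2L]
    for (line in lines) {
      for (s in seq_len(nrow(line) - 1L)) {
        a <- line[s, ]; b <- line[s + 1L, ]
        ## endpoint-to-edge distances both ways
        d1 <- min(.pointSegDist(a[1L], a[2L], rx1, ry1, rx2, ry2),
                  .pointSegDist(b[1L], b[2L], rx1, ry1, rx2, ry2))
        d2 <- min(.pointSegDist(rx1, ry1, a[1L], a[2L], b[1L], b[2L]),
                  .pointSegDist(rx2, ry2, a[1L], a[2L], b[1L], b[2L]))
        d <- min(d1, d2)
        if (d < best) best <- d
        if (best == 0) return(0)
        if (d1 > 0 && d2 > 0) {
          ## proper crossing check only when bounding distance small
          for (k in seq_along(rx1)) {
            if (.segIntersects(c(rx1[k], ry1[k]), c(rx2[k], ry2[k]), a, b))
              return(0)
          }
        }
      }
    }
  }
  best
}
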