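## Seeded synthetic multispectral scenes with exact ground truth.
##
## Default spectra sit strictly inside (raft) or outside (water, cloud)
## every condition of the detection rule with at least 0.01 reflectance
## margin, so the noise-free pipeline must recover planted truth
## exactly, and small band noise cannot flip the contract.

#' Spectral preset for the scene generator
#'
#' @param name preset label
#' @param means named per-band mean reflectances, each in [0, 1.5]
#' @param noiseSd i.i.d. Gaussian band noise standard deviation
#'   (truncated at 0 reflectance)
#' @return a validated preset (list)
#' @export
spectrumPreset <- function(name, means, noiseSd = 0) {
  if (any(means < 0) || any(means > 1.5))
    stop("preset means must lie in [0, 1.5]", call. = FALSE)
  if (noiseSd < 0) stop("noise must be >= 0", call. = FALSE)
  structure(list(name = name, means = means, noiseSd = noiseSd),
            class = "SpectrumPreset")
}

#' Default presets
#'
#' Clear Caribbean water (fails the detection rule because red exceeds
#' both NIR bands), a floating raft spectrum (satisfies all five
#' conditions with >= 0.01 margin), and a bright cloud. The default
#' noise of 0.002 reflectance approximates L2A radiometric scatter over
#' dark water.
#'
#' @param noiseSd Gaussian band noise, reflectance units
#' @return a \code{\link{spectrumPreset}}
#' @export
waterPreset <- function(noiseSd = 0.002) {
  spectrumPreset("water",
                 c(b02 = 0.045, b03 = 0.04, b04 = 0.03, b05 = 0.025,
                   b08 = 0.02, b8A = 0.015, b11 = 0.005),
                 noiseSd)
}

#' @rdname waterPreset
#' @export
raftPreset <- function(noiseSd = 0.002) {
  spectrumPreset("raft",
                 c(b02 = 0.04, b03 = 0.05, b04 = 0.04, b05 = 0.05,
                   b08 = 0.09, b8A = 0.06, b11 = 0.03),
                 noiseSd)
}

#' @rdname waterPreset
#' @export
cloudPreset <- function(noiseSd = 0.002) {
  spectrumPreset("cloud",
                 c(b02 = 0.3, b03 = 0.3, b04 = 0.3, b05 = 0.3,
                   b08 = 0.3, b8A = 0.3, b11 = 0.3),
                 noiseSd)
}

#' Raft footprint specification
#'
#' Footprints contain exactly \code{sizePixels} pixels: an ellipse (2:1
#' axis ratio) takes the \code{sizePixels} pixels closest to the center
#' in elliptical distance; a filament takes them along a line at
#' \code{orientation}.
#'
#' @param center \code{c(row, col)} center pixel
#' @param shape \code{"ellipse"} or \code{"filament"}
#' @param sizePixels number of pixels (>= 1)
#' @param orientation degrees counterclockwise from the row axis
#' @return a raft spec (list)
#' @export
raftSpec <- function(center, shape = c("ellipse", "filament"),
                     sizePixels = 10, orientation = 0) {
  shape <- match.arg(shape)
  if (sizePixels < 1) stop("sizePixels must be >= 1", call. = FALSE)
  structure(list(center = center, shape = shape,
                 sizePixels = as.integer(sizePixels),
                 orientation = orientation), class = "RaftSpec")
}

.footprint <- function(spec, nr, nc) {
  ci <- spec$center[1L]; cj <- spec$center[2L]
  if (ci < 1 || ci > nr || cj < 1 || cj > nc)
    stop("raft center outside grid", call. = FALSE)
  th <- spec$orientation * pi / 180
  if (spec$shape == "ellipse") {
    rad <- ceiling(sqrt(spec$sizePixels)) + 2L
    ii <- pmax(1L, ci - rad):pmin(nr, ci + rad)
    jj <- pmax(1L, cj - rad):pmin(nc, cj + rad)
    gi <- rep(ii, times = length(jj)); gj <- rep(jj, each = length(ii))
    u <- (gi - ci) * cos(th) + (gj - cj) * sin(th)
    v <- -(gi - ci) * sin(th) + (gj - cj) * cos(th)
    d <- u^2 + (2 * v)^2              # 2:1 axis ratio
    ord <- order(d, gi, gj)
    sel <- ord[seq_len(min(spec$sizePixels, length(ord)))]
    cbind(gi[sel], gj[sel])
  } else {
    t <- seq(-spec$sizePixels, spec$sizePixels, by = 0.25)
    gi <- round(ci + t * cos(th)); gj <- round(cj + t * sin(th))
    ok <- gi >= 1 & gi <= nr & gj >= 1 & gj <= nc
    pts <- unique(cbind(gi[ok], gj[ok])[order(abs(t[ok])), , drop = FALSE])
    pts[seq_len(min(spec$sizePixels, nrow(pts))), , drop = FALSE]
  }
}

.S2_BANDS <- c("b02", "b03", "b04", "b05", "b08", "b8A", "b11")

#' Generate a seeded open-water scene
#'
#' Bands are drawn i.i.d. around the water preset means (Gaussian,
#' truncated at 0); the SCL layer is all water (code 6); the truth mask
#' is empty. Identical arguments give bit-identical scenes; the caller's
#' RNG state is left untouched.
#'
#' @param shape \code{c(nrow, ncol)}
#' @param waterPreset a \code{\link{spectrumPreset}}
#' @param seed integer seed
#' @param pixelSizeM pixel side, meters (default 20)
#' @param tile MGRS tile id (default \code{"T16QDJ"})
#' @param datetime acquisition time (default 2022-07-15T16:09:01 UTC)
#' @return a \code{\linkS4class{SyntheticScene}}
#' @export
makeScene <- function(shape, waterPreset = SargassumRafts::waterPreset(),
                      seed = 1L, pixelSizeM = 20, tile = "T16QDJ",
                      datetime = "2022-07-15 16:09:01") {
  nr <- shape[1L]; nc <- shape[2L]
  zn <- mgrsZone(tile)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  bands <- list()
  for (b in .S2_BANDS) {
    mu <- waterPreset$means[[b]]
    v <- if (waterPreset$noiseSd > 0)
      pmax(matrix(stats::rnorm(nr * nc, mu, waterPreset$noiseSd), nr, nc), 0)
    else matrix(mu, nr, nc)
    bands[[b]] <- v
  }
  scene <- Scene(bands, transform = c(3e5, 2.1e6, pixelSizeM, pixelSizeM),
                 crs = zn$epsg, datetime = datetime, tileId = tile,
                 sensor = "S2")
  scl <- SCLLayer(matrix(6L, nr, nc), transform = scene@transform,
                  crs = zn$epsg)
  new("SyntheticScene", scene = scene, scl = scl,
      truth = matrix(FALSE, nr, nc), seed = as.integer(seed))
}

#' Plant raft footprints into a synthetic scene
#'
#' Raft pixels are overwritten with the raft spectrum (plus preset
#' noise) and the truth mask becomes the union of the footprints;
#' overlapping rafts merge. RNG state is derived from the scene seed so
#' the result is a pure function of (scene, specs, preset).
#'
#' @param synthetic a \code{\linkS4class{SyntheticScene}}
#' @param specs list of \code{\link{raftSpec}}s (a single spec is
#'   accepted)
#' @param raftPreset a \code{\link{spectrumPreset}}
#' @return the updated \code{\linkS4class{SyntheticScene}}
#' @export
plantRafts <- function(synthetic, specs,
                       raftPreset = SargassumRafts::raftPreset()) {
  if (inherits(specs, "RaftSpec")) specs <- list(specs)
  if (length(specs) == 0L) return(synthetic)
  scene <- synthetic@scene
  d <- dim(scene)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((synthetic@seed * 7L + 101L) %% .Machine$integer.max)
  truth <- synthetic@truth
  bands <- scene@bands
  for (spec in specs) {
    fp <- .footprint(spec, d[1L], d[2L])
    idx <- (fp[, 2L] - 1L) * d[1L] + fp[, 1L]
    for (b in names(bands)) {
      mu <- raftPreset$means[[b]]
      val <- if (raftPreset$noiseSd > 0)
        pmax(stats::rnorm(length(idx), mu, raftPreset$noiseSd), 0)
      else rep(mu, length(idx))
      bands[[b]][idx] <- val
    }
    truth[idx] <- TRUE
  }
  scene@bands <- bands
  initialize(synthetic, scene = scene, truth = truth)
}

#' Add opaque clouds to a synthetic scene
#'
#' Cloud pixels take the (bright) cloud spectrum and SCL code 9 (cloud
#' high probability); truth is cleared underneath -- an obscured raft is
#' not detectable ground truth.
#'
#' @param synthetic a \code{\linkS4class{SyntheticScene}}
#' @param footprints a logical matrix, or a list of discs
#'   \code{list(center = c(row, col), radius = pixels)}
#' @param cloudPreset a \code{\link{spectrumPreset}}
#' @return the updated \code{\linkS4class{SyntheticScene}}
#' @export
addClouds <- function(synthetic, footprints,
                      cloudPreset = SargassumRafts::cloudPreset()) {
  scene <- synthetic@scene
  d <- dim(scene)
  cl <- matrix(FALSE, d[1L], d[2L])
  if (is.matrix(footprints)) {
    cl <- cl | footprints
  } else {
    for (f in footprints) {
      gi <- rep(seq_len(d[1L]), times = d[2L])
      gj <- rep(seq_len(d[2L]), each = d[1L])
      cl[(gi - f$center[1L])^2 + (gj - f$center[2L])^2 <= f$radius^2] <- TRUE
    }
  }
  if (!any(cl)) return(synthetic)
  idx <- which(cl)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed((synthetic@seed * 7L + 211L) %% .Machine$integer.max)
  bands <- scene@bands
  for (b in names(bands)) {
    mu <- cloudPreset$means[[b]]
    val <- if (cloudPreset$noiseSd > 0)
      pmax(stats::rnorm(length(idx), mu, cloudPreset$noiseSd), 0)
    else rep(mu, length(idx))
    bands[[b]][idx] <- val
  }
  scene@bands <- bands
  scl <- synthetic@scl
  codes <- scl@codes
  codes[idx] <- 9L
  truth <- synthetic@truth
  truth[idx] <- FALSE
  initialize(synthetic, scene = scene,
             scl = SCLLayer(codes, scl@transform, scl@crs), truth = truth)
}
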