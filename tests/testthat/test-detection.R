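test_that("detection rule evaluates the printed conjunction with strict inequalities", {
  mkpx <- function(b04, b08, b8A, b11)
    toyScene(1, 1, bands = list(b04 = matrix(b04, 1, 1), b08 = matrix(b08, 1, 1),
                                b8A = matrix(b8A, 1, 1), b11 = matrix(b11, 1, 1)))
  val <- function(sc) maskValues(eq1Mask(sc))[1, 1]
  expect_true(val(mkpx(0.05, 0.10, 0.06, 0.03)))      # all five hold
  expect_false(val(mkpx(0.05, 0.10, 0.07, 0.03)))     # b8A == threshold: ties fail
  expect_false(val(mkpx(0.10, 0.11, 0.06, 0.03)))     # b04 == threshold
  expect_false(val(mkpx(0.05, 0.10, 0.06, 0.05)))     # b11 == threshold
  expect_false(val(mkpx(0.03, 0.02, 0.015, 0.005)))   # clear water: b04 >= b8A
  expect_false(val(mkpx(0.05, 0.05, 0.06, 0.03)))     # b04 == b08 tie fails
})

test_that("detection rule matches per-pixel brute force on random scenes", {
  set.seed(11)
  for (rep in 1:5) {
    b04 <- matrix(runif(64 * 64, 0, 0.15), 64, 64)
    b08 <- matrix(runif(64 * 64, 0, 0.15), 64, 64)
    b8A <- matrix(runif(64 * 64, 0, 0.15), 64, 64)
    b11 <- matrix(runif(64 * 64, 0, 0.10), 64, 64)
    nd <- randomMask(64, 64, 0.05)
    sc <- toyScene(64, 64, bands = list(b04 = b04, b08 = b08, b8A = b8A,
                                        b11 = b11), nodata = nd)
    got <- maskValues(eq1Mask(sc))
    expect_identical(got, bruteEq1(b04, b08, b8A, b11, nd))
    expect_false(any(got & nd))     # nodata never detected
  }
})

test_that("FAI closed forms hold", {
  mk <- function(r, n, s) toyScene(3, 3, bands = list(
    red = matrix(r, 3, 3), nir = matrix(n, 3, 3), swir = matrix(s, 3, 3)))
  lam <- c(655, 865, 1609)
  # baseline formula evaluated independently
  expected <- 0.10 - 0.05 - (0.03 - 0.05) * (865 - 655) / (1609 - 655)
  fai <- computeFAI(mk(0.05, 0.10, 0.03), lam)
  expect_lt(max(abs(faiValues(fai) - expected)), 1e-12)
  # flat spectrum: no red edge
  expect_equal(max(abs(faiValues(computeFAI(mk(0.07, 0.07, 0.07), lam)))), 0)
  # zero baseline: FAI collapses to the NIR reflectance
  expect_equal(faiValues(computeFAI(mk(0, 0.42, 0), lam))[1, 1], 0.42)
  expect_error(computeFAI(mk(0.1, 0.1, 0.1), c(865, 655, 1609)),
               "parameter error")
})

test_that("FAI is strictly increasing in NIR and propagates nodata", {
  nd <- matrix(FALSE, 2, 2); nd[1, 1] <- TRUE
  mk <- function(n) toyScene(2, 2, bands = list(red = matrix(0.05, 2, 2),
    nir = matrix(n, 2, 2), swir = matrix(0.03, 2, 2)), nodata = nd)
  f1 <- faiValues(computeFAI(mk(0.10)))
  f2 <- faiValues(computeFAI(mk(0.11)))
  expect_true(is.na(f1[1, 1]))
  expect_equal(f2[2, 2] - f1[2, 2], 0.01)
})

test_that("SCL masking removes excluded classes and matches brute force", {
  allTrue <- DetectionMask(matrix(TRUE, 8, 8), stages = "eq1")
  cloud <- SCLLayer(matrix(9L, 8, 8))
  expect_false(any(maskValues(applySCLMask(allTrue, cloud))))
  water <- SCLLayer(matrix(6L, 8, 8))
  expect_true(all(maskValues(applySCLMask(allTrue, water))))
  set.seed(21)
  codes <- matrix(sample(0:11, 64, replace = TRUE), 8, 8)
  got <- maskValues(applySCLMask(allTrue, SCLLayer(codes)))
  manual <- matrix(TRUE, 8, 8)
  for (i in 1:8) for (j in 1:8)
    manual[i, j] <- !(codes[i, j] %in% c(0, 1, 3, 8, 9, 10))
  expect_identical(got, manual)
  expect_identical(maskStages(applySCLMask(allTrue, water)), c("eq1", "scl"))
  expect_error(applySCLMask(allTrue, SCLLayer(matrix(6L, 3, 3))),
               "geometry error")
})

test_that("local entropy matches the sliding-window histogram oracle", {
  set.seed(31)
  band <- matrix(runif(12 * 12, 0, 0.1), 12, 12)
  nd <- randomMask(12, 12, 0.1)
  for (w in c(3, 5)) {
    # fixed quantization interval matched to the band's dynamic range
    H <- localEntropy(band, nd, w = w, Q = 8, range = c(0, 0.1))
    expect_lt(max(abs(H - bruteEntropy(band, nd, w, 8, c(0, 0.1)))), 1e-10)
    # scene-relative (min-max) mode
    Hmm <- localEntropy(band, nd, w = w, Q = 8, range = NULL)
    expect_lt(max(abs(Hmm - bruteEntropy(band, nd, w, 8, NULL))), 1e-10)
  }
})

test_that("entropy filter keeps uniform fields and removes checkerboard texture", {
  # constant b8A: zero entropy everywhere, mask unchanged
  sc <- toyScene(10, 10)
  m <- DetectionMask(matrix(TRUE, 10, 10), stages = "eq1")
  out <- entropyFilter(m, sc, DetectionParams(entropyMax = 0.0))
  expect_true(all(maskValues(out)))
  expect_identical(maskStages(out), c("eq1", "entropy"))

  # two-level checkerboard: interior windows near 1 bit (13/25 vs 12/25
  # split of a 5x5 window), so an 0.5-bit cutoff clears the interior
  cb <- matrix(0.02, 12, 12)
  cb[(row(cb) + col(cb)) %% 2 == 0] <- 0.06
  scCb <- toyScene(12, 12, bands = list(b04 = cb * 0 + 0.03, b08 = cb,
                                        b8A = cb, b11 = cb * 0 + 0.005))
  H <- localEntropy(cb, NULL, w = 5, Q = 32)
  p <- c(13, 12) / 25
  expect_equal(H[6, 6], -sum(p * log2(p)), tolerance = 1e-12)
  expect_lt(abs(H[6, 6] - 1), 0.01)
  filtered <- entropyFilter(DetectionMask(matrix(TRUE, 12, 12), "eq1"), scCb,
                            DetectionParams(entropyMax = 0.5))
  expect_false(any(maskValues(filtered)[3:10, 3:10]))

  expect_error(localEntropy(cb, matrix(TRUE, 12, 12)), "degenerate")
})

test_that("minimum-size filter thresholds components inclusively", {
  v <- matrix(FALSE, 8, 8)
  v[2, 2] <- TRUE                     # isolated pixel
  v[5, 5:6] <- TRUE                   # exactly 2 pixels
  m <- minSizeFilter(DetectionMask(v, "eq1"), DetectionParams(minSize = 2))
  expect_false(maskValues(m)[2, 2])
  expect_true(all(maskValues(m)[5, 5:6]))
  expect_identical(maskStages(m), c("eq1", "minsize"))

  set.seed(41)
  for (conn in c(4, 8)) {
    rv <- randomMask(20, 20, 0.35)
    got <- maskValues(minSizeFilter(DetectionMask(rv),
                                    DetectionParams(minSize = 3,
                                                    connectivity = conn)))
    lab <- bruteLabel(rv, conn)
    keep <- matrix(FALSE, 20, 20)
    if (max(lab) > 0) {
      sizes <- table(lab[lab > 0])
      for (k in as.integer(names(sizes)[sizes >= 3])) keep[lab == k] <- TRUE
    }
    expect_identical(got, keep)
  }
})

test_that("component labels are row-major and match flood-fill brute force", {
  v <- matrix(FALSE, 5, 5)
  v[1, 4] <- TRUE; v[3, 1] <- TRUE; v[4, 2] <- TRUE  # diagonal pair
  lab8 <- labelComponents(v, 8)
  expect_identical(lab8[1, 4], 1L)        # first in row-major scan
  expect_identical(lab8[3, 1], 2L)
  expect_identical(lab8[4, 2], 2L)        # diagonal joins under 8
  lab4 <- labelComponents(v, 4)
  expect_identical(lab4[4, 2], 3L)        # separate under 4
  set.seed(51)
  for (conn in c(4, 8)) for (rep in 1:3) {
    rv <- randomMask(15, 15, 0.4)
    expect_identical(labelComponents(rv, conn), bruteLabel(rv, conn))
  }
})

test_that("every cleaning stage only removes detections (monotone pipeline)", {
  set.seed(61)
  syn <- plantRafts(makeScene(c(48, 48), waterPreset(0.004), seed = 99),
                    list(raftSpec(c(12, 12), "ellipse", 8),
                         raftSpec(c(30, 35), "filament", 7, 45)),
                    raftPreset(0.004))
  syn <- addClouds(syn, list(list(center = c(40, 10), radius = 5)))
  m0 <- eq1Mask(syn@scene)
  m1 <- applySCLMask(m0, syn@scl)
  m2 <- entropyFilter(m1, syn@scene)
  m3 <- minSizeFilter(m2)
  expect_true(all(maskValues(m1) <= maskValues(m0)))
  expect_true(all(maskValues(m2) <= maskValues(m1)))
  expect_true(all(maskValues(m3) <= maskValues(m2)))
  expect_identical(maskStages(m3), c("eq1", "scl", "entropy", "minsize"))
})
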