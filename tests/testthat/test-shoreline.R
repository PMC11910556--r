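test_that("half-plane split yields one straight shoreline polyline", {
  lw <- matrix(FALSE, 8, 8); lw[, 1:4] <- TRUE     # land west, water east
  coast <- deriveShoreline(lw, transform = c(0, 160, 20, 20))
  expect_length(coastLines(coast), 1)
  l <- coastLines(coast)[[1]]
  expect_true(all(l[, 1] == 80))                    # column boundary at c=4
  expect_setequal(range(l[, 2]), c(0, 160))
})

test_that("an island produces one closed ring of 4 pixel sides", {
  lw <- matrix(FALSE, 5, 5); lw[3, 3] <- TRUE
  coast <- deriveShoreline(lw, transform = c(0, 5, 1, 1))
  expect_length(coastLines(coast), 1)
  l <- coastLines(coast)[[1]]
  expect_identical(l[1, ], l[nrow(l), ])            # closed
  # perimeter = 4 pixel sides
  per <- sum(sqrt(rowSums((l[-1, , drop = FALSE] - l[-nrow(l), , drop = FALSE])^2)))
  expect_equal(per, 4)
})

test_that("shoreline edge set equals brute-force enumeration of land/water pairs", {
  set.seed(91)
  for (rep in 1:5) {
    lw <- randomMask(10, 10, 0.5)
    if (all(lw) || !any(lw)) next
    coast <- deriveShoreline(lw, transform = c(0, 10, 1, 1))
    # decompose polylines into unit edges keyed by their midpoints
    mids <- c()
    for (l in coastLines(coast)) for (k in seq_len(nrow(l) - 1)) {
      a <- l[k, ]; b <- l[k + 1, ]
      n <- max(abs(b - a))
      for (s in seq_len(n))   # split merged collinear runs into unit edges
        mids <- c(mids, paste((a[1] + (b[1] - a[1]) * (s - 0.5) / n),
                              (a[2] + (b[2] - a[2]) * (s - 0.5) / n)))
    }
    ref <- c()
    for (i in 1:10) for (j in 1:10) {
      if (j < 10 && lw[i, j] != lw[i, j + 1])
        ref <- c(ref, paste(j, 10 - i + 0.5))       # vertical edge at c=j
      if (i < 10 && lw[i, j] != lw[i + 1, j])
        ref <- c(ref, paste(j - 0.5, 10 - i))       # horizontal edge at r=i
    }
    expect_setequal(mids, ref)
  }
})

test_that("degenerate all-land / all-water grids are rejected", {
  expect_error(deriveShoreline(matrix(TRUE, 4, 4)), "degenerate")
  expect_error(deriveShoreline(matrix(FALSE, 4, 4)), "degenerate")
})

test_that("beach mask = bare-in-every-epoch within the shore buffer", {
  # 16x16: land cols 1:8, water cols 9:16; strip col 8 bare everywhere,
  # col 7 vegetated in one epoch
  nr <- 16; nc <- 16
  mk <- function(vegCols) {
    e <- matrix(3L, nr, nc); e[, 9:16] <- 1L; e[, vegCols] <- 2L; e
  }
  epochs <- list(dry1 = mk(1:6), rainy1 = mk(1:7), dry2 = mk(1:6))
  tr <- c(0, nr * 20, 20, 20)
  stack <- CoverStack(epochs, seasons = c("dry", "rainy", "dry"),
                      transform = tr)
  lw <- matrix(FALSE, nr, nc); lw[, 1:8] <- TRUE
  coast <- deriveShoreline(lw, transform = tr)
  bm <- deriveBeachMask(stack, coast, maxShoreDistanceM = 50, seasonal = TRUE)
  expect_true(all(bm@values[, 8]))      # bare in all epochs, 10 m from shore
  expect_false(any(bm@values[, 7]))     # vegetated in the rainy epoch
  expect_false(any(bm@values[, 9:16]))  # water

  # brute-force set algebra on a random stack
  set.seed(101)
  codes <- lapply(1:3, function(k) matrix(sample(0:3, nr * nc, TRUE), nr, nc))
  stack2 <- CoverStack(codes, transform = tr)
  # buffer chosen off the 10/30/50... m grid of center distances so the
  # comparison never sits on a float boundary
  bm2 <- deriveBeachMask(stack2, coast, maxShoreDistanceM = 75)
  bare <- codes[[1]] == 3 & codes[[2]] == 3 & codes[[3]] == 3
  ctr <- pixelCenter(tr, rep(1:nr, nc), rep(1:nc, each = nr))
  dshore <- abs(ctr[, 1] - 160)         # straight shoreline at x = 160
  near <- matrix(dshore <= 75, nr, nc)
  expect_identical(bm2@values, bare & near)
})

test_that("beach mask is anti-monotone in epochs and monotone in buffer", {
  nr <- 12; nc <- 12
  tr <- c(0, nr * 20, 20, 20)
  lw <- matrix(FALSE, nr, nc); lw[, 1:6] <- TRUE
  coast <- deriveShoreline(lw, transform = tr)
  set.seed(111)
  codes <- lapply(1:4, function(k)
    matrix(sample(c(3L, 3L, 2L, 1L), nr * nc, TRUE), nr, nc))
  m3 <- deriveBeachMask(CoverStack(codes[1:3], transform = tr), coast, 100)
  m4 <- deriveBeachMask(CoverStack(codes, transform = tr), coast, 100)
  expect_true(all(m4@values <= m3@values))          # extra epoch never grows
  mNarrow <- deriveBeachMask(CoverStack(codes[1:3], transform = tr), coast, 40)
  expect_true(all(mNarrow@values <= m3@values))     # wider buffer never shrinks
  # every beach pixel is bare in epoch 1
  expect_true(all(codes[[1]][m3@values] == 3L))
})

test_that("seasonal mode requires dry and rainy epochs", {
  tr <- c(0, 80, 20, 20)
  lw <- matrix(FALSE, 4, 4); lw[, 1:2] <- TRUE
  coast <- deriveShoreline(lw, transform = tr)
  stack <- CoverStack(list(a = matrix(3L, 4, 4), b = matrix(3L, 4, 4)),
                      seasons = c("dry", "dry"), transform = tr)
  expect_error(deriveBeachMask(stack, coast, seasonal = TRUE), "rainy")
  expect_silent(deriveBeachMask(stack, coast, seasonal = FALSE))
})

test_that("NDVI cover helper separates water, vegetation and bare", {
  red <- matrix(c(0.05, 0.02, 0.10, 0.20), 2, 2)
  nir <- matrix(c(0.02, 0.30, 0.12, 0.10), 2, 2)
  code <- coverFromNDVI(red, nir)
  expect_identical(code[1, 1], 1L)   # dark, NDVI < 0: water
  expect_identical(code[2, 1], 2L)   # NDVI 0.875: vegetation
  expect_identical(code[1, 2], 3L)   # NDVI 0.09: bare
  expect_identical(code[2, 2], 3L)   # negative NDVI but bright NIR: bare
})
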