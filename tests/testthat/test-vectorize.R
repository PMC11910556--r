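test_that("a 2x2 block polygonizes to one 1600 m2 polygon", {
  sc <- toyScene(8, 8)
  v <- matrix(FALSE, 8, 8); v[3:4, 5:6] <- TRUE
  polys <- maskToPolygons(v, sc)
  expect_length(polys, 1)
  expect_identical(polys[[1]]$pixelCount, 4L)
  area <- SargassumRafts:::.ringSignedArea(polys[[1]]$rings[[1]])
  expect_equal(area, 1600)
  expect_false(polys[[1]]$edgeTouching)
})

test_that("diagonal pixels form one component under 8- and two under 4-connectivity", {
  sc <- toyScene(6, 6)
  v <- matrix(FALSE, 6, 6); v[2, 2] <- TRUE; v[3, 3] <- TRUE
  expect_length(maskToPolygons(v, sc, 8), 1)
  expect_length(maskToPolygons(v, sc, 4), 2)
})

test_that("polygonize/rasterize is the identity, holes included", {
  sc <- toyScene(9, 9)
  ring <- matrix(TRUE, 9, 9); ring[4:6, 4:6] <- FALSE; ring[1, ] <- FALSE
  polys <- maskToPolygons(ring, sc, 4)
  expect_length(polys, 1)
  expect_length(polys[[1]]$rings, 2)   # outer + hole
  signs <- sign(vapply(polys[[1]]$rings, SargassumRafts:::.ringSignedArea, 0))
  expect_identical(sort(signs), c(-1, 1))
  back <- rasterizePolygons(polys, dim(sc), geoTransform(sc))
  expect_identical(back, ring)

  set.seed(71)
  for (conn in c(4, 8)) for (rep in 1:5) {
    rv <- randomMask(16, 16, 0.45)
    polys <- maskToPolygons(rv, sc <- toyScene(16, 16), conn)
    expect_identical(rasterizePolygons(polys, c(16L, 16L), geoTransform(sc)),
                     rv)
  }
})

test_that("polygon area equals pixel count times pixel area (shoelace)", {
  set.seed(72)
  sc <- toyScene(14, 14)
  rv <- randomMask(14, 14, 0.4)
  polys <- maskToPolygons(rv, sc, 8)
  for (p in polys) {
    shoelace <- sum(vapply(p$rings, SargassumRafts:::.ringSignedArea, 0))
    expect_equal(shoelace, p$pixelCount * 400, tolerance = 1e-12)
  }
})

test_that("distance to coast: plane-geometry cases", {
  # 2 km-wide square centered 5 km from a straight north-south coast
  tr <- c(0, 20000, 20, 20)
  coast <- Coastline(cbind(x = c(0, 0), y = c(0, 20000)), crs = "EPSG:32616")
  sq <- list(rings = list(cbind(x = c(4000, 6000, 6000, 4000, 4000),
                                y = c(4000, 4000, 6000, 6000, 4000))))
  expect_equal(distanceToCoast(sq, coast), 4)
  # polygon crossing the coastline
  cross <- list(rings = list(cbind(x = c(-500, 500, 500, -500, -500),
                                   y = c(100, 100, 900, 900, 100))))
  expect_identical(distanceToCoast(cross, coast), 0)
  # coastline vertex strictly inside the polygon
  inside <- list(rings = list(cbind(x = c(-10, 10, 10, -10, -10) * 1000,
                                    y = c(-1, -1, 30, 30, -1) * 1000)))
  expect_identical(distanceToCoast(inside, coast), 0)
  expect_error(distanceToCoast(sq, list()), "contract violation")
})

test_that("distance to coast matches the densified brute-force oracle", {
  set.seed(81)
  sc <- toyScene(20, 20)
  for (rep in 1:12) {
    v <- matrix(FALSE, 20, 20)
    i <- sample(3:18, 1); j <- sample(3:18, 1)
    v[i + 0:1, j + 0:1] <- TRUE
    poly <- maskToPolygons(v, sc)[[1]]
    # coastline kept strictly east of the raft so the pairs never intersect
    # (exact-zero intersection behavior is covered above)
    pts <- cbind(x = 3e5 + runif(3, 500, 1200), y = 2.1e6 - runif(3, -300, 700))
    coast <- Coastline(pts)
    d <- distanceToCoast(poly, coast)
    ref <- bruteMinDist(poly$rings, coastLines(coast)) / 1000
    expect_lt(abs(d - ref), 1e-6)
  }
})

test_that("distance is invariant under translation and reflection", {
  sc <- toyScene(12, 12)
  v <- matrix(FALSE, 12, 12); v[4:6, 7:9] <- TRUE
  poly <- maskToPolygons(v, sc)[[1]]
  coast <- Coastline(cbind(x = c(299000, 299000), y = c(2.09e6, 2.11e6)))
  d0 <- distanceToCoast(poly, coast)
  shift <- c(12345, -6789)
  polyT <- list(rings = lapply(poly$rings, function(r)
    cbind(r[, 1] + shift[1], r[, 2] + shift[2])))
  coastT <- Coastline(lapply(coastLines(coast), function(l)
    cbind(l[, 1] + shift[1], l[, 2] + shift[2])))
  expect_equal(distanceToCoast(polyT, coastT), d0, tolerance = 1e-12)
  # mirror x -> -x
  polyM <- list(rings = lapply(poly$rings, function(r)
    cbind(-r[, 1], r[, 2])))
  coastM <- Coastline(lapply(coastLines(coast), function(l)
    cbind(-l[, 1], l[, 2])))
  expect_equal(distanceToCoast(polyM, coastM), d0, tolerance = 1e-12)
})

test_that("location classification follows beach > other seaweed > ocean", {
  comp <- list(pixels = c(5L, 6L))
  beach <- matrix(FALSE, 4, 4); benthic <- matrix(FALSE, 4, 4)
  expect_identical(classifyLocation(comp, beach, benthic), "ocean")
  benthic[5] <- TRUE
  expect_identical(classifyLocation(comp, beach, benthic), "other_seaweed")
  beach[6] <- TRUE
  expect_identical(classifyLocation(comp, beach, benthic), "beach")
  expect_identical(classifyLocation(comp, NULL, NULL), "ocean")
})

test_that("records carry the full attribute table", {
  syn <- plantRafts(makeScene(c(32, 32), waterPreset(0), seed = 5),
                    list(raftSpec(c(6, 6), "ellipse", 10),
                         raftSpec(c(15, 20), "ellipse", 5),
                         raftSpec(c(28, 10), "filament", 6, 60)),
                    raftPreset(0))
  mask <- eq1Mask(syn@scene)
  polys <- maskToPolygons(mask, syn@scene)
  coast <- Coastline(cbind(x = c(299000, 299000), y = c(2.0e6, 2.2e6)),
                     crs = "EPSG:32616")
  rec <- buildRecords(polys, syn@scene, coastline = coast)
  expect_identical(rec$id, 1:3)
  expect_identical(rec$tile_id, rep("T16QDJ", 3))
  # 10-pixel raft at 20 m: exactly 0.004 km2
  expect_equal(rec$area_km2[1], 0.004, tolerance = 1e-12)
  expect_equal(sum(rec$area_km2), sum(truthMask(syn)) * 400 / 1e6,
               tolerance = 1e-9)
  # ids ordered row-major by first pixel
  firsts <- vapply(polys, function(p) {
    i <- (p$pixels - 1) %% 32 + 1; j <- (p$pixels - 1) %/% 32 + 1
    min((i - 1) * 32 + j)
  }, 0)
  expect_identical(order(firsts), 1:3)
  expect_true(all(rec$distance_to_coast_km > 0))
  expect_true(all(rec$location_class == "ocean"))
  expect_false(any(is.na(rec$distance_bin)))
  # without coastline the distance attributes are absent
  rec2 <- buildRecords(polys, syn@scene)
  expect_true(all(is.na(rec2$distance_to_coast_km)))
  expect_true(all(is.na(rec2$distance_bin)))
})

test_that("distance bins follow the color-scale edges", {
  expect_identical(SargassumRafts:::.distanceBin(c(0, 0.5, 1, 3, 7, 50)),
                   c("0-1", "0-1", "0-1", "1-5", "5-10", ">10"))
})

test_that("GeoJSON round trips geometry and all attributes", {
  syn <- plantRafts(makeScene(c(24, 24), waterPreset(0), seed = 9),
                    list(raftSpec(c(8, 8), "ellipse", 10),
                         raftSpec(c(18, 18), "filament", 5, 20)),
                    raftPreset(0))
  polys <- maskToPolygons(eq1Mask(syn@scene), syn@scene)
  coast <- Coastline(cbind(x = c(299000, 299000), y = c(2.0e6, 2.2e6)),
                     crs = "EPSG:32616")
  rec <- buildRecords(polys, syn@scene, coastline = coast)
  p <- file.path(tempdir(), "rafts.geojson")
  writeGeoJSON(rec, p)
  obj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_identical(obj$type, "FeatureCollection")
  # RFC 7946: coordinates are WGS84 lon/lat in plausible Caribbean range
  c0 <- obj$features[[1]]$geometry$coordinates[[1]][[1]]
  expect_true(c0[[1]] > -95 && c0[[1]] < -80)
  expect_true(c0[[2]] > 10 && c0[[2]] < 25)
  back <- readGeoJSON(p)
  expect_identical(back$id, rec$id)
  expect_identical(back$pixel_count, rec$pixel_count)
  expect_equal(back$area_km2, rec$area_km2, tolerance = 1e-9)
  expect_equal(back$distance_to_coast_km, rec$distance_to_coast_km,
               tolerance = 1e-9)
  expect_identical(back$location_class, rec$location_class)
  expect_identical(back$edge_touching, rec$edge_touching)
  expect_identical(format(back$acquisition_date[1], "%Y-%m-%d %H:%M:%S",
                          tz = "UTC"),
                   format(rec$acquisition_date[1], "%Y-%m-%d %H:%M:%S",
                          tz = "UTC"))
  # projected vertices recovered within 1e-6 degrees ~ 0.1 m
  for (k in seq_len(nrow(rec)))
    expect_lt(max(abs(back$geometry[[k]][[1]] - rec$geometry[[k]][[1]])), 0.2)
})

test_that("empty record sets and absent distances serialize cleanly", {
  sc <- toyScene(8, 8)
  rec <- buildRecords(list(), sc)
  expect_identical(nrow(rec), 0L)
  p <- file.path(tempdir(), "empty.geojson")
  writeGeoJSON(rec, p)
  obj <- jsonlite::fromJSON(p, simplifyVector = FALSE)
  expect_length(obj$features, 0)

  v <- matrix(FALSE, 8, 8); v[3, 3:4] <- TRUE
  rec1 <- buildRecords(maskToPolygons(v, sc), sc)   # no coastline
  p1 <- file.path(tempdir(), "nodist.geojson")
  writeGeoJSON(rec1, p1)
  expect_match(paste(readLines(p1), collapse = ""),
               "\"distance_to_coast_km\":null")
  back <- readGeoJSON(p1)
  expect_true(is.na(back$distance_to_coast_km[1]))
  expect_error(readGeoJSON(file.path(tempdir(), "absent.geojson")), "error")
})

test_that("attribute CSV export mirrors the table", {
  sc <- toyScene(8, 8)
  v <- matrix(FALSE, 8, 8); v[2:3, 2:3] <- TRUE
  rec <- buildRecords(maskToPolygons(v, sc), sc)
  p <- file.path(tempdir(), "attrs.csv")
  recordsToCSV(rec, p)
  df <- read.csv(p)
  expect_identical(df$pixel_count, 4L)
  expect_identical(df$tile_id, "T16QDJ")
  expect_false("geometry" %in% names(df))
})
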