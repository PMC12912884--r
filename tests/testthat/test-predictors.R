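test_that("nearest-neighbour alignment reproduces block structure and brute force", {
  tmpl <- geo_raster(matrix(0, 4, 4), xmin = 0, ymin = 0, cell = 0.25)
  src <- geo_raster(matrix(1:16, 4, 4), xmin = 0, ymin = 0, cell = 0.25)
  expect_equal(align_raster(src, tmpl)$values, src$values)

  # 2x2 source upsampled to 4x4: each value fills a 2x2 block
  src2 <- geo_raster(matrix(c(1, 3, 2, 4), 2, 2), xmin = 0, ymin = 0, cell = 0.5)
  up <- align_raster(src2, tmpl)
  expect_equal(up$values,
               matrix(c(1, 1, 3, 3, 1, 1, 3, 3, 2, 2, 4, 4, 2, 2, 4, 4), 4, 4))

  # random 10x10 -> 7x7 against brute-force nearest-centre lookup
  set.seed(6)
  src3 <- geo_raster(matrix(stats::rnorm(100), 10, 10),
                     xmin = 20, ymin = -10, cell = 0.1)
  tmpl3 <- geo_raster(matrix(0, 7, 7), xmin = 20.05, ymin = -9.95,
                      cell = 0.13)
  got <- align_raster(src3, tmpl3)
  cc <- raster_centres(tmpl3)
  sc <- raster_centres(src3)
  for (i in 1:7) for (j in 1:7) {
    si <- which.min(abs(sc$y - cc$y[i]))
    sj <- which.min(abs(sc$x - cc$x[j]))
    expect_equal(got$values[i, j], src3$values[si, sj])
  }

  far <- geo_raster(matrix(0, 3, 3), xmin = 100, ymin = 50, cell = 0.1)
  expect_error(align_raster(src3, far), "disjoint")
})

test_that("Horn slope handles flat, inclined and random terrain", {
  flat <- geo_raster(matrix(250, 6, 6), xmin = 30, ymin = -20, cell = 0.05)
  expect_true(all(slope_from_elevation(flat)$values == 0))

  # plane rising 1 m per 100 m northward -> atan(0.01) = 0.5729 degrees
  cell <- 0.01
  nr <- 9
  lat_m <- (nr:1 - 0.5) * cell * 111320   # metres north of the south edge
  plane <- geo_raster(matrix(rep(lat_m * 0.01, 6), nr, 6),
                      xmin = 10, ymin = 0, cell = cell)
  sl <- slope_from_elevation(plane)
  expect_equal(sl$values[3:7, 3:4],
               matrix(atan(0.01) * 180 / pi, 5, 2), tolerance = 1e-6)

  # translation invariance
  plane2 <- plane; plane2$values <- plane2$values + 500
  expect_equal(slope_from_elevation(plane2)$values, sl$values,
               tolerance = 1e-9)

  # random 5x5 against an independent stencil implementation
  set.seed(12)
  z <- matrix(stats::runif(25, 0, 300), 5, 5)
  r <- geo_raster(z, xmin = 33, ymin = -18, cell = 0.04)
  got <- slope_from_elevation(r)
  ref <- horn_slope_reference(z, 0.04, raster_centres(r)$y)
  expect_equal(got$values[2:4, 2:4], ref[2:4, 2:4], tolerance = 1e-9)

  expect_error(slope_from_elevation(geo_raster(matrix(0, 2, 5), 0, 0, 1)),
               "3 x 3")
})

test_that("land-cover reclassification is a pure lookup that preserves nodata", {
  r <- geo_raster(matrix(10, 3, 3), xmin = 0, ymin = 0, cell = 1)
  out <- reclassify_lulc(r, data.frame(from = 10, to = 1))
  expect_true(all(out$values == 1))

  r2 <- geo_raster(matrix(c(10, NA, 20, 20), 2, 2), xmin = 0, ymin = 0, cell = 1)
  out2 <- reclassify_lulc(r2, data.frame(from = c(10, 20), to = c(1, 5)))
  expect_true(is.na(out2$values[is.na(r2$values)]))

  # permuted 6-class checkerboard equals per-cell lookup
  set.seed(13)
  v <- matrix(sample(1:6, 36, TRUE), 6, 6)
  perm <- sample(1:6)
  mapping <- data.frame(from = 1:6, to = perm)
  out3 <- reclassify_lulc(geo_raster(v, 0, 0, 1), mapping)
  expect_equal(out3$values, matrix(perm[v], 6, 6))

  expect_error(reclassify_lulc(geo_raster(v, 0, 0, 1),
                               data.frame(from = 1:5, to = 1:5)),
               "unmapped LULC class")
})

test_that("point extraction uses half-open cell ownership", {
  r <- geo_raster(matrix(1:12, 3, 4), xmin = 0, ymin = 0, cell = 1)
  # cell centre
  expect_equal(extract_at_points(r, 0.5, 2.5), r$values[1, 1])
  # shared vertical edge belongs to the eastern cell
  expect_equal(extract_at_points(r, 1, 2.5), r$values[1, 2])
  # shared horizontal edge belongs to the southern cell
  expect_equal(extract_at_points(r, 0.5, 2), r$values[2, 1])
  expect_warning(v <- extract_at_points(r, 99, 99), "outside")
  expect_true(is.na(v))

  # 100 random points against brute-force index arithmetic
  set.seed(14)
  lon <- stats::runif(100, 0, 4); lat <- stats::runif(100, 0, 3)
  got <- extract_at_points(r, lon, lat)
  oracle <- vapply(1:100, function(i) {
    r$values[3 - floor(lat[i]), floor(lon[i]) + 1]
  }, numeric(1))
  expect_equal(got, oracle)
})

test_that("great-circle distances match closed forms and exhaustive search", {
  expect_equal(haversine_m(0, 0, 0, 1), 111195, tolerance = 1 / 111195)
  harb <- cbind(35, -20)
  expect_equal(distance_to_nearest(35, -20, harb), 0)

  set.seed(15)
  qlon <- stats::runif(50, 30, 40); qlat <- stats::runif(50, -25, -10)
  feats <- cbind(stats::runif(5, 30, 40), stats::runif(5, -25, -10))
  got <- distance_to_nearest(qlon, qlat, feats)
  oracle <- vapply(1:50, function(i) {
    min(vapply(1:5, function(j) {
      haversine_m(qlon[i], qlat[i], feats[j, 1], feats[j, 2])
    }, numeric(1)))
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-12)

  # reordering features changes nothing; adding features never increases
  got_rev <- distance_to_nearest(qlon, qlat, feats[5:1, ])
  expect_equal(got, got_rev)
  more <- rbind(feats, cbind(stats::runif(3, 30, 40), stats::runif(3, -25, -10)))
  expect_true(all(distance_to_nearest(qlon, qlat, more) <= got + 1e-9))

  # polyline densification: distance to a meridian segment from 1 degree east
  line <- list(rbind(c(0, -1), c(0, 1)))
  d <- distance_to_nearest(1, 0, line, spacing = 100)
  expect_equal(d, 111195, tolerance = 100 / 111195)

  expect_error(distance_to_nearest(1, 1, list()), "empty")
})

test_that("pseudo-absence sampling is balanced, bounded and seeded", {
  set.seed(16)
  pres <- data.frame(lon = stats::runif(40, 32, 36),
                     lat = stats::runif(40, -22, -18))
  abs1 <- sample_pseudo_absences(pres, seed = 5)
  expect_equal(nrow(abs1), nrow(pres))
  expect_true(all(abs1$lon >= min(pres$lon) & abs1$lon <= max(pres$lon)))
  expect_true(all(abs1$lat >= min(pres$lat) & abs1$lat <= max(pres$lat)))
  expect_identical(abs1, sample_pseudo_absences(pres, seed = 5))
  expect_false(identical(abs1, sample_pseudo_absences(pres, seed = 6)))

  # masked sampling stays in the mask; impossible masks exhaust the budget
  mask <- rect_poly(33, 34, -21, -20)
  am <- sample_pseudo_absences(pres, n = 50, seed = 7, mask = mask)
  expect_true(all(point_in_polygon(am$lon, am$lat, mask)))
  expect_error(
    sample_pseudo_absences(pres, n = 5, seed = 8,
                           valid_fun = function(lon, lat) rep(FALSE, length(lon)),
                           max_attempts = 500),
    "budget exhausted"
  )
})

test_that("pseudo-absences are uniform across bounding-box quadrants", {
  pres <- data.frame(lon = c(30, 40), lat = c(-25, -10))
  draws <- sample_pseudo_absences(pres, n = 10000, seed = 99)
  qx <- draws$lon > 35; qy <- draws$lat > -17.5
  obs <- table(qx, qy)
  chi <- stats::chisq.test(as.vector(obs), p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.001)
})

test_that("the model table merges rasters, distances and the binary response", {
  ls1 <- tiny_landscape()
  set.seed(17)
  pres <- data.frame(lon = stats::runif(3, 33.2, 35.8),
                     lat = stats::runif(3, -19.8, -16.2))
  abs <- data.frame(lon = stats::runif(3, 33.2, 35.8),
                    lat = stats::runif(3, -19.8, -16.2))
  tab <- build_model_table(pres, abs, ls1$elevation, ls1$slope, ls1$lulc,
                           ls1$roads, ls1$harbours)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$presence, c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_s3_class(tab$lulc, "factor")
  expect_equal(levels(tab$lulc), lulc_levels())
  # every raster value matches a direct lookup
  expect_equal(tab$elevation,
               extract_at_points(ls1$elevation, tab$lon, tab$lat))
  expect_equal(as.integer(tab$lulc),
               as.integer(extract_at_points(ls1$lulc, tab$lon, tab$lat)))

  # a point off the raster is dropped with a logged count
  abs2 <- abs; abs2$lon[1] <- 60
  expect_message(
    suppressWarnings(
      tab2 <- build_model_table(pres, abs2, ls1$elevation, ls1$slope,
                                ls1$lulc, ls1$roads, ls1$harbours)
    ),
    "dropped 1 row"
  )
  expect_equal(nrow(tab2), 5)
})
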