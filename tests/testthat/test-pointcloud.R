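test_that("SOR flags exactly the distant point and nothing on regular grids", {
  cl <- point_cloud(cbind(c(0:4, 100), 0, 0))
  out <- sor_denoise(cl, k = 2, alpha = 1)
  expect_equal(out$outliers$x, 100)
  expect_equal(nrow(out$inliers), 5)
  expect_equal(nrow(out$inliers) + nrow(out$outliers), nrow(cl))

  expect_equal(nrow(sor_denoise(cl, k = 2, alpha = 1e9)$outliers), 0)

  # identical mean-kNN distances: sd = 0, threshold = mean, nothing exceeds it
  square <- point_cloud(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0))
  expect_equal(nrow(sor_denoise(square, k = 2, alpha = 1)$outliers), 0)

  # a bounded grid does NOT have identical d_i: its four corners are the
  # most isolated points and the classical rule flags exactly them
  grid <- point_cloud(cbind(rep(1:10, 10), rep(1:10, each = 10), 0))
  out <- sor_denoise(grid, k = 4, alpha = 1)$outliers
  expect_identical(sor_oracle(as.matrix(grid), 4, 1),
                   seq_len(100) %in% as.integer(rownames(out)))
  expect_setequal(paste(out$x, out$y),
                  c("1 1", "10 1", "1 10", "10 10"))

  expect_error(sor_denoise(point_cloud(cbind(1:3, 0, 0)), k = 8), "more than k")
})

test_that("SOR agrees with the brute-force kNN-distance oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(30:200, 1)
    xyz <- matrix(rnorm(3 * n), ncol = 3)
    if (seed %% 2 == 0) xyz[1:3, ] <- xyz[1:3, ] * 40 # plant gross outliers
    cl <- point_cloud(xyz)
    k <- sample(3:10, 1)
    res <- sor_denoise(cl, k = k, alpha = 1)
    truth <- sor_oracle(xyz, k, 1)
    got <- rep(FALSE, n)
    got[as.integer(rownames(res$outliers))] <- TRUE
    expect_identical(got, unname(truth))
  }
})

test_that("cloth simulation labels a bare sloped plane entirely as ground", {
  set.seed(7)
  gx <- runif(3000, 0, 10); gy <- runif(3000, 0, 8)
  flat <- point_cloud(cbind(gx, gy, 0.01 * gx))
  lab <- classify_ground(flat, class_threshold = 0.05)
  expect_true(all(lab$label == "ground"))
})

test_that("cloth simulation separates ground from plant canopies", {
  truth <- field_truth(2, 3, seed = 21)
  cloud <- generate_field_cloud(truth)
  is_plant <- cloud$g == 160 # generator colour book
  lab <- classify_ground(cloud, class_threshold = 0.1)
  plane_h <- cloud$z - aerialpheno:::plane_z(truth$plane, cloud$x, cloud$y)
  expect_gt(mean(lab$label[!is_plant] == "ground"), 0.95)
  expect_gt(mean(lab$label[plane_h > 0.3] == "aboveground"), 0.95)
})

test_that("a class threshold above plant height labels everything ground", {
  set.seed(2)
  g <- cbind(runif(2000, 0, 5), runif(2000, 0, 5), 0)
  plant <- cbind(runif(200, 2, 3), runif(200, 2, 3), runif(200, 0, 0.4))
  cl <- point_cloud(rbind(g, plant))
  lab <- classify_ground(cl, class_threshold = 1.0)
  expect_true(all(lab$label == "ground"))
  expect_error(classify_ground(cl[0, ]), "empty")
})

test_that("TIN rasterization is exact for planes and no-data outside the hull", {
  flat <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = 0)
  g <- rasterize_tin(flat, 0.25)
  expect_true(all(g$values == 0))

  tilt <- data.frame(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1), z = c(0, 1, 1, 0))
  g2 <- rasterize_tin(tilt, 0.1)
  expect_equal(g2$values[5, 6], 0.55, tolerance = 1e-9)

  tri <- data.frame(x = c(0, 1, 0), y = c(0, 0, 1), z = 0)
  g3 <- rasterize_tin(tri, 0.1)
  expect_true(is.na(g3$values[1, 10])) # top-right cell centre outside hull

  expect_error(rasterize_tin(data.frame(x = 1:5, y = 1:5, z = 1), 0.1), "collinear")
})

test_that("CHM differencing clips noise, converts units, and propagates no-data", {
  ground <- raster_grid(matrix(0, 4, 4), res = 1)
  surface <- raster_grid(matrix(0, 4, 4), res = 1)
  expect_true(all(build_chm(ground, surface)$values == 0))

  surface$values[2, 3] <- 0.8
  expect_equal(build_chm(ground, surface)$values[2, 3], 80)

  surface$values[1, 1] <- -0.01
  expect_equal(build_chm(ground, surface)$values[1, 1], 0)

  surface$values[4, 4] <- NA
  expect_true(is.na(build_chm(ground, surface)$values[4, 4]))

  off <- raster_grid(matrix(0, 4, 4), res = 2)
  expect_error(build_chm(ground, off), "misaligned")
})

test_that("CHM is monotone in the surface", {
  set.seed(5)
  ground <- raster_grid(matrix(runif(36), 6, 6))
  surface <- raster_grid(matrix(runif(36, 0.5, 2), 6, 6))
  base <- build_chm(ground, surface)
  for (i in 1:10) {
    s2 <- surface
    cell <- sample(36, 1)
    s2$values[cell] <- s2$values[cell] + runif(1, 0, 1)
    expect_true(all(build_chm(ground, s2)$values >= base$values))
  }
})

test_that("slope removal recovers the plane exactly and is idempotent", {
  set.seed(1)
  ref <- data.frame(x = runif(30, 0, 10), y = runif(30, 0, 10))
  ref$z <- 0.02 * ref$x + 0.01 * ref$y + 3
  out <- remove_slope(point_cloud(as.matrix(ref)), ref)
  expect_equal(unname(out$plane), c(0.02, 0.01, 3), tolerance = 1e-9)

  # refit on corrected points is flat
  corr <- as.data.frame(out$corrected)
  p2 <- fit_plane(corr)
  expect_lt(max(abs(p2[1:2])), 1e-9)

  # idempotent: second application changes nothing beyond 1e-9
  out2 <- remove_slope(out$corrected, corr)
  expect_lt(max(abs(out2$corrected$z - out$corrected$z)), 1e-9)

  # flat field: correction is exactly -gamma
  flat <- data.frame(x = runif(10), y = runif(10), z = 5)
  rf <- remove_slope(point_cloud(as.matrix(flat)), flat)
  expect_equal(rf$corrected$z, rep(0, 10), tolerance = 1e-12)

  expect_error(fit_plane(data.frame(x = 1:5, y = 2 * (1:5), z = 1)), "collinear")
})

test_that("slope removal applies the same correction to rasters", {
  g <- raster_grid(outer(10:1, 1:8, function(r, c) 0.05 * c), res = 1, origin = c(0, 10))
  # cell centres: x = c - 0.5, y = 10 - (r - 0.5); values = 0.05 * c = 0.05 (x + 0.5)
  ref <- data.frame(x = c(0.5, 7.5, 0.5, 7.5), y = c(9.5, 9.5, 0.5, 0.5))
  ref$z <- 0.05 * (ref$x + 0.5)
  out <- remove_slope(g, ref)
  expect_lt(max(abs(out$corrected$values)), 1e-9)
})
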