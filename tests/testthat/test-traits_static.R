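test_that("percentile canopy height matches direct enumeration", {
  chm <- raster_grid(matrix(1:100, 10, 10))
  box <- c(0, 0, 10, 10)
  expect_equal(canopy_height(chm, box, 0.10), mean(91:100))
  expect_equal(canopy_height(chm, box, 1.0), mean(1:100))
  expect_equal(canopy_height(raster_grid(matrix(80, 5, 5)), c(0, 0, 5, 5), 0.37), 80)
  expect_true(is.na(canopy_height(raster_grid(matrix(NA_real_, 4, 4)), c(0, 0, 4, 4))))
})

test_that("canopy height is permutation-invariant and monotone", {
  set.seed(9)
  vals <- runif(48, 0, 150)
  base <- canopy_height(raster_grid(matrix(vals, 6, 8)), c(0, 0, 6, 8), 0.1)
  for (i in 1:5) {
    perm <- matrix(sample(vals), 6, 8)
    expect_equal(canopy_height(raster_grid(perm), c(0, 0, 6, 8), 0.1), base)
  }
  for (i in 1:5) {
    up <- vals
    cell <- sample(48, 1)
    up[cell] <- up[cell] + runif(1, 0, 50)
    expect_gte(canopy_height(raster_grid(matrix(up, 6, 8)), c(0, 0, 6, 8), 0.1), base)
  }
})

test_that("seedling counting is exact with and without clod distractors", {
  truth <- field_truth(1, 1, seed = 31)
  ortho <- generate_orthomosaic(truth, px_per_m = 40, mode = "seedling")
  chm <- generate_truth_chm(truth, px_per_m = 40, mode = "seedling", ortho = ortho)
  box <- aligned_plot_box_full(truth, 1, scale = 0.9, px_per_m = 40)
  expect_equal(count_seedlings(chm, ortho, box), 18)

  # clods share height and size but fail the green gate
  ortho_c <- generate_orthomosaic(truth, px_per_m = 40, mode = "seedling", n_clods = 3)
  chm_c <- generate_truth_chm(truth, px_per_m = 40, mode = "seedling", ortho = ortho_c)
  expect_equal(count_seedlings(chm_c, ortho_c, box), 18)

  # bare plot
  bare <- field_truth(1, 1, seed = 32, n_seedlings = 0)
  ortho_b <- generate_orthomosaic(bare, px_per_m = 40, mode = "seedling")
  chm_b <- generate_truth_chm(bare, px_per_m = 40, mode = "seedling")
  expect_equal(count_seedlings(chm_b, ortho_b, box), 0)
})

test_that("canopy coverage tracks the painted green fraction", {
  for (cov in c(0, 0.2, 0.4, 0.7, 1.0)) {
    truth <- field_truth(1, 1, seed = 41, coverage = cov)
    ortho <- generate_orthomosaic(truth, px_per_m = 40)
    chm <- generate_truth_chm(truth, px_per_m = 40)
    box <- aligned_plot_box_full(truth, 1, scale = 0.7, px_per_m = 40)
    cci <- canopy_coverage(chm, ortho, box)
    expect_lt(abs(cci - cov), 0.02)
    expect_gte(cci, 0); expect_lte(cci, 1)
  }
})

test_that("vegetative indices match hand-computed pixel cases", {
  one <- function(r, g, b) {
    vegetative_indices(toy_rgb(matrix(r, 2, 2), matrix(g, 2, 2), matrix(b, 2, 2)),
                       c(0, 0, 2, 2))
  }
  vi <- one(50, 150, 50)
  expect_equal(vi$exg, 0.8)
  expect_equal(vi$exg_norm, 0.6)
  expect_equal(vi$vari, 2 / 3)
  expect_equal(vi$ndyi, 0.5)
  expect_equal(vi$gli, 0.5)
  expect_equal(vi$nvi, 0.5)
  expect_equal(vi$exr, 1.4 * 0.2 - 0.6)

  grey <- one(120, 120, 120)
  expect_equal(grey$exg, 0)
  expect_equal(grey$nvi, 0)
  expect_equal(grey$vari, 0)
  expect_equal(grey$ndyi, 0)

  green <- one(0, 255, 0)
  expect_equal(green$exg, 2)
  expect_equal(green$exg_norm, 1)

  black <- one(0, 0, 0)
  expect_true(all(is.na(unlist(black))))
})

test_that("chromatic indices are invariant to intensity scaling", {
  set.seed(6)
  r <- matrix(sample(10:120, 36, TRUE), 6, 6)
  g <- matrix(sample(10:120, 36, TRUE), 6, 6)
  b <- matrix(sample(10:120, 36, TRUE), 6, 6)
  base <- vegetative_indices(toy_rgb(r, g, b), c(0, 0, 6, 6))
  for (s in c(0.5, 1.7, 2)) {
    sc <- vegetative_indices(toy_rgb(r * s, g * s, b * s), c(0, 0, 6, 6))
    for (nm in c("exg", "exg_norm", "exr", "nvi", "gli", "vari", "ndyi")) {
      expect_equal(sc[[nm]], base[[nm]], tolerance = 1e-12)
    }
  }
})

test_that("GLCM texture features match their closed forms and oracle", {
  const <- raster_grid(matrix(42, 8, 8))
  gf <- glcm_features(const, c(0, 0, 8, 8))
  expect_equal(gf$asm, 1)
  expect_equal(gf$dissimilarity, 0)

  checker <- raster_grid(outer(1:8, 1:8, function(r, c) (r + c) %% 2))
  gc <- glcm_features(checker, c(0, 0, 8, 8), levels = 2, angles_deg = 0)
  expect_equal(gc$asm, 0.5)
  expect_equal(gc$dissimilarity, 1)

  # brute-force sum(P^2) oracle on random regions
  set.seed(8)
  for (i in 1:5) {
    m <- matrix(sample(0:7, 64, TRUE), 8, 8)
    gfx <- glcm_features(raster_grid(m), c(0, 0, 8, 8), levels = 8, angles_deg = 0)
    # enumerate all horizontal pairs both directions
    P <- matrix(0, 8, 8)
    for (r in 1:8) for (c in 1:7) {
      i1 <- m[r, c] + 1; i2 <- m[r, c + 1] + 1
      P[i1, i2] <- P[i1, i2] + 1; P[i2, i1] <- P[i2, i1] + 1
    }
    P <- P / sum(P)
    expect_equal(gfx$asm, sum(P^2), tolerance = 1e-12)
    expect_equal(gfx$dissimilarity,
                 sum(P * abs(outer(0:7, 0:7, "-"))), tolerance = 1e-12)
  }

  tiny <- raster_grid(matrix(1, 1, 1))
  expect_true(is.na(glcm_features(tiny, c(0, 0, 1, 1))$asm))
})

test_that("trait values respect their documented ranges on random scenes", {
  set.seed(12)
  for (i in 1:5) {
    truth <- field_truth(1, 1, seed = 100 + i)
    ortho <- generate_orthomosaic(truth, px_per_m = 40)
    chm <- generate_truth_chm(truth, px_per_m = 40)
    box <- aligned_plot_box_full(truth, 1, scale = 0.7, px_per_m = 40)
    vi <- vegetative_indices(ortho, box)
    expect_true(vi$exg_norm >= 0 && vi$exg_norm <= 1)
    expect_true(vi$vari >= -1 && vi$vari <= 1)
    expect_true(vi$ndyi >= -1 && vi$ndyi <= 1)
    cci <- canopy_coverage(chm, ortho, box)
    expect_true(cci >= 0 && cci <= 1)
    expect_gte(canopy_height(chm, box), 0)
    gf <- glcm_features(chm, box)
    expect_true(gf$asm > 0 && gf$asm <= 1)
    expect_gte(gf$dissimilarity, 0)
  }
})
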