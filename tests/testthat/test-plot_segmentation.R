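test_that("ISODATA threshold reaches the class-mean midpoint fixed point", {
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- isodata_threshold(img)
  expect_equal(res$threshold, 105)
  expect_identical(res$mask, img > 105)

  expect_equal(isodata_threshold(matrix(c(0, 255), 2, 2))$threshold, 127.5)
  expect_error(isodata_threshold(matrix(5, 3, 3)), "constant")
})

# mask of an n_rows x n_cols plot grid with gap_px-wide bare gaps
grid_mask <- function(n_rows, n_cols, plot_px = 30, gap_px = 6) {
  h <- n_rows * plot_px + (n_rows - 1) * gap_px
  w <- n_cols * plot_px + (n_cols - 1) * gap_px
  m <- matrix(FALSE, h, w)
  for (r in seq_len(n_rows)) for (c in seq_len(n_cols)) {
    r0 <- (r - 1) * (plot_px + gap_px); c0 <- (c - 1) * (plot_px + gap_px)
    m[(r0 + 1):(r0 + plot_px), (c0 + 1):(c0 + plot_px)] <- TRUE
  }
  m
}

test_that("Hough detection finds every gap and respects orientation", {
  m <- grid_mask(4, 5)
  hl <- detect_grid_lines(m, "horizontal")
  vl <- detect_grid_lines(m, "vertical")
  expect_gte(length(hl$positions), 5)
  expect_gte(length(vl$positions), 6)
  true_h <- c(33, 69, 105) # gap centres between 30-px plots with 6-px gaps
  true_v <- c(33, 69, 105, 141)
  for (t in true_h) expect_true(any(abs(hl$positions - t) <= 3))
  for (t in true_v) expect_true(any(abs(vl$positions - t) <= 3))

  all_veg <- matrix(TRUE, 40, 40)
  expect_length(detect_grid_lines(all_veg, "horizontal")$positions, 0)

  one_h_gap <- matrix(TRUE, 40, 40)
  one_h_gap[19:22, ] <- FALSE
  expect_length(detect_grid_lines(one_h_gap, "vertical")$positions, 0)
  expect_gt(length(detect_grid_lines(one_h_gap, "horizontal")$positions), 0)
})

test_that("adjacent lines merge to cluster means with a minimum gap", {
  ls <- aerialpheno:::line_set("horizontal", c(100, 102, 240), 300)
  expect_equal(merge_adjacent_lines(ls, 10)$positions, c(101, 240))

  sep <- aerialpheno:::line_set("vertical", c(50, 150, 250), 300)
  expect_equal(merge_adjacent_lines(sep, 10)$positions, c(50, 150, 250))

  tight <- aerialpheno:::line_set("vertical", c(10, 14, 18, 22), 300)
  expect_equal(merge_adjacent_lines(tight, 10)$positions, 16)
  merged <- merge_adjacent_lines(aerialpheno:::line_set("vertical", 1:50, 300), 8)
  expect_true(all(diff(merged$positions) >= 8))
})

test_that("manual lines are unioned, absorbed, and bounds-checked", {
  ls <- aerialpheno:::line_set("horizontal", c(40, 80), 120)
  expect_equal(add_manual_lines(ls, 60)$positions, c(40, 60, 80))
  expect_equal(add_manual_lines(ls, 80)$positions, c(40, 80))
  expect_error(add_manual_lines(ls, 130), "outside")
})

test_that("plot assembly labels cells and reports count mismatches", {
  hl <- aerialpheno:::line_set("horizontal", c(30, 60, 90), 120)
  vl <- aerialpheno:::line_set("vertical", c(30, 60, 90, 120), 150)
  grid <- assemble_plot_grid(hl, vl, trial_layout(4, 5), c(120, 150))
  expect_equal(nrow(grid), 20)
  expect_equal(grid$plot_id[1], "R1C1")
  expect_equal(unlist(grid[1, c("r0", "c0", "r1", "c1")]), c(r0 = 0, c0 = 0, r1 = 30, c1 = 30))
  # disjoint rectangles
  area <- sum((grid$r1 - grid$r0) * (grid$c1 - grid$c0))
  expect_equal(area, 120 * 150)

  expect_error(assemble_plot_grid(hl, vl, trial_layout(4, 6), c(120, 150)),
               "expects 4 x 6 .* 4 x 5")
})

test_that("mask scaling shrinks about centroids with scale^2 area ratio", {
  hl <- aerialpheno:::line_set("horizontal", 40, 80)
  vl <- aerialpheno:::line_set("vertical", 100, 200)
  g <- assemble_plot_grid(hl, vl, trial_layout(2, 2), c(80, 200))
  s <- scale_plot_grid(g, 0.5)
  expect_equal(s$c1 - s$c0, rep(50, 4))
  expect_equal(s$r1 - s$r0, rep(20, 4))
  expect_lt(max(abs((s$c0 + s$c1) / 2 - (g$c0 + g$c1) / 2)), 0.51)

  expect_identical(scale_plot_grid(g, 1), g)
  expect_error(scale_plot_grid(g, 0), "scale")
  expect_error(scale_plot_grid(g, 1.2), "scale")

  set.seed(4)
  for (sc in c(0.3, 0.7, 0.9)) {
    s2 <- scale_plot_grid(g, sc)
    ratio <- ((s2$r1 - s2$r0) * (s2$c1 - s2$c0)) / ((g$r1 - g$r0) * (g$c1 - g$c0))
    expect_true(all(abs(ratio - sc^2) < 0.1))
  }
  # composition within 1-px rounding
  ab <- scale_plot_grid(scale_plot_grid(g, 0.9), 0.8)
  once <- scale_plot_grid(g, 0.72)
  expect_true(all(abs(as.matrix(ab[, 4:7]) - as.matrix(once[, 4:7])) <= 1))
})

test_that("end-to-end segmentation recovers the layout on synthetic CHMs", {
  for (case in list(c(2, 3, 5), c(4, 5, 11))) {
    truth <- field_truth(case[1], case[2], seed = case[3])
    chm <- generate_truth_chm(truth, px_per_m = 20)
    # crop to the ROI rectangle (the aligned frame)
    res <- 0.05; ext <- truth$extent
    box <- c(round((ext[4] - truth$roi$y[1]) / res), round((truth$roi$x[1] - ext[1]) / res),
             round((ext[4] - truth$roi$y[3]) / res), round((truth$roi$x[2] - ext[1]) / res))
    aligned <- crop_raster(chm, box)
    grid <- segment_plots(aligned, truth$layout)
    expect_equal(nrow(grid), case[1] * case[2])
    for (i in seq_len(nrow(grid))) {
      p <- truth$plots[truth$plots$plot_id == grid$plot_id[i], ]
      px <- world_to_aligned(truth, (p$x0 + p$x1) / 2, (p$y0 + p$y1) / 2, res)
      expect_true(px[, "row"] >= grid$r0[i] && px[, "row"] < grid$r1[i])
      expect_true(px[, "col"] >= grid$c0[i] && px[, "col"] < grid$c1[i])
    }
    # deterministic: no randomized steps
    expect_identical(as.data.frame(segment_plots(aligned, truth$layout)),
                     as.data.frame(grid))
  }
})
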