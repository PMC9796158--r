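# Shared fixtures: the cloud-to-aligned-CHM pipeline on a synthetic field,
# and coordinate conversions between the world frame and the aligned
# (ROI-cropped) pixel frame.

run_chm_pipeline <- function(truth, sigma_z = 0, outlier_frac = 0,
                             chm_res = 0.05, ...) {
  cloud <- generate_field_cloud(truth, sigma_z = sigma_z,
                                outlier_frac = outlier_frac, ...)
  build_aligned_chm(cloud, truth$roi, ortho = NULL, chm_res = chm_res)
}

# world (x, y) -> aligned-frame pixel (col, row); the aligned frame is the
# ROI rectangle sampled at 1/chm_res px per metre
world_to_aligned <- function(truth, x, y, chm_res = 0.05) {
  cbind(col = (x - truth$roi$x[1]) / chm_res,
        row = (truth$roi$y[1] - y) / chm_res)
}

# aligned-frame half-open pixel box of plot i at a mask scale
aligned_plot_box <- function(truth, i, scale = 1, chm_res = 0.05) {
  p <- truth$plots[i, ]
  tlbr <- world_to_aligned(truth, c(p$x0, p$x1), c(p$y1, p$y0), chm_res)
  r0 <- tlbr[1, "row"]; r1 <- tlbr[2, "row"]
  c0 <- tlbr[1, "col"]; c1 <- tlbr[2, "col"]
  rc <- (r0 + r1) / 2; cc <- (c0 + c1) / 2
  hh <- (r1 - r0) * scale / 2; hw <- (c1 - c0) * scale / 2
  c(round(rc - hh), round(cc - hw), round(rc + hh), round(cc + hw))
}

# half-open pixel box of plot i in the FULL field raster frame (as
# produced by generate_orthomosaic / generate_truth_chm), at a mask scale
aligned_plot_box_full <- function(truth, i, scale = 1, px_per_m = 40) {
  p <- truth$plots[i, ]
  H <- round((truth$extent[4] - truth$extent[2]) * px_per_m)
  r0 <- H - p$y1 * px_per_m; r1 <- H - p$y0 * px_per_m
  c0 <- p$x0 * px_per_m; c1 <- p$x1 * px_per_m
  rc <- (r0 + r1) / 2; cc <- (c0 + c1) / 2
  hh <- (r1 - r0) * scale / 2; hw <- (c1 - c0) * scale / 2
  c(round(rc - hh), round(cc - hw), round(rc + hh), round(cc + hw))
}

# brute-force O(n^2) statistical-outlier-removal oracle
sor_oracle <- function(xyz, k, alpha) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  mean_knn <- vapply(seq_len(n), function(i) mean(sort(d[i, -i])[seq_len(k)]), 0)
  mean_knn > mean(mean_knn) + alpha * stats::sd(mean_knn)
}

# deterministic small RGB raster
toy_rgb <- function(r, g, b) {
  arr <- array(0, c(nrow(r), ncol(r), 3))
  arr[, , 1] <- r; arr[, , 2] <- g; arr[, , 3] <- b
  raster_grid(arr, bitdepth = 8L)
}
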