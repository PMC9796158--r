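#' Percentile canopy height of a plot
#'
#' Mean of the CHM cells at or above the `1 - top_fraction` quantile of
#' the plot box: the classical H90th (`top_fraction = 0.10`), H95th
#' (0.05) and H50th (0.50) height statistics. Height plots are normally
#' sampled at mask scale 0.25-0.3 to avoid inter-plot overlap.
#'
#' @param chm a CHM [raster_grid] in cm.
#' @param box half-open pixel box `c(r0, c0, r1, c1)` (e.g. a `plot_grid`
#'   row).
#' @param top_fraction fraction of the highest cells to average, in (0, 1].
#' @return mean height in cm, or `NA` if the box holds no data.
#' @export
canopy_height <- function(chm, box, top_fraction = 0.10) {
  if (top_fraction <= 0 || top_fraction > 1) stop("top_fraction must be in (0, 1]", call. = FALSE)
  v <- crop_raster(chm, box)$values
  v <- v[!is.na(v)]
  if (!length(v)) return(NA_real_)
  q <- stats::quantile(v, 1 - top_fraction, names = FALSE, type = 7)
  mean(v[v >= q])
}

#' Count seedlings in a plot
#'
#' Early-establishment seedling counting from aligned CHM and RGB (plot
#' masks at scale ~0.9): (1) a seedling mask keeps CHM cells at or above
#' the plot's 95th height percentile; (2) mask pixels whose normalized
#' excess-green is below `green_min` are dropped (removing soil clods and
#' water); (3) one 3x3 binary erosion separates touching seedlings;
#' (4) 8-connected components of at least `min_area` pixels are counted.
#'
#' @param chm,rgb aligned [raster_grid]s (cm heights; 8-bit RGB).
#' @param box half-open pixel box.
#' @param green_min normalized ExG gate in [0, 1] (default 0.40).
#' @param min_area minimum component size in px after erosion (default 4).
#' @return integer seedling count (0 for an empty plot).
#' @export
count_seedlings <- function(chm, rgb, box, green_min = 0.40, min_area = 4) {
  hv <- crop_raster(chm, box)$values
  if (!any(!is.na(hv))) return(0L)
  q <- stats::quantile(hv[!is.na(hv)], 0.95, names = FALSE, type = 7)
  q <- q - 1e-7 * (abs(q) + 1) # tolerate float ties from interpolation
  mask <- !is.na(hv) & hv >= q & hv > 0
  if (!any(mask)) return(0L)
  col <- crop_raster(rgb, box)$values
  exg_n <- exg_norm_plane(col)
  mask <- mask & !is.na(exg_n) & exg_n >= green_min
  mask <- binary_erode3(mask)
  comps <- connected_components(mask)
  if (comps$n == 0) return(0L)
  sizes <- tabulate(comps$labels[comps$labels > 0], nbins = comps$n)
  sum(sizes >= min_area)
}

exg_norm_plane <- function(rgb_arr) {
  s <- rgb_arr[, , 1] + rgb_arr[, , 2] + rgb_arr[, , 3]
  g <- rgb_arr[, , 2] / s
  r <- rgb_arr[, , 1] / s
  b <- rgb_arr[, , 3] / s
  exg <- 2 * g - r - b
  exg[s == 0] <- NA
  (exg + 1) / 3
}

# One pass of 3x3 binary erosion (border pixels treated as background).
binary_erode3 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  if (h < 3 || w < 3) return(matrix(FALSE, h, w))
  p <- matrix(FALSE, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- mask
  out <- p[2:(h + 1), 2:(w + 1)]
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out & p[2:(h + 1) + dr, 2:(w + 1) + dc]
  }
  out
}

# 8-connected component labelling by breadth-first flood fill.
connected_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  n <- 0L
  idx <- which(mask)
  if (!length(idx)) return(list(labels = labels, n = 0L))
  for (start in idx) {
    if (labels[start] != 0L) next
    n <- n + 1L
    queue <- start
    labels[start] <- n
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      r <- (cur - 1L) %% h + 1L
      c <- (cur - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- r + dr; cc <- c + dc
        ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
        if (!any(ok)) next
        nb <- (cc[ok] - 1L) * h + rr[ok]
        nb <- nb[mask[nb] & labels[nb] == 0L]
        if (length(nb)) {
          labels[nb] <- n
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  list(labels = labels, n = n)
}

# Local mean filter with edge-renormalized square window (integral image).
local_mean <- function(v, window = 51) {
  stopifnot(window %% 2 == 1)
  h <- nrow(v); w <- ncol(v)
  half <- (window - 1) / 2
  vz <- v; vz[is.na(vz)] <- 0
  ones <- !is.na(v) + 0
  ii <- function(m) {
    s <- apply(m, 2, cumsum)
    t(apply(s, 1, cumsum))
  }
  S <- ii(vz); N <- ii(ones)
  r0 <- pmax(seq_len(h) - half - 1, 0); r1 <- pmin(seq_len(h) + half, h)
  c0 <- pmax(seq_len(w) - half - 1, 0); c1 <- pmin(seq_len(w) + half, w)
  pick <- function(M, ri, ci) ifelse(ri == 0 | ci == 0, 0, M[cbind(pmax(ri, 1), pmax(ci, 1))])
  R1 <- rep(r1, w); R0 <- rep(r0, w); C1 <- rep(c1, each = h); C0 <- rep(c0, each = h)
  box_sum <- function(M) pick(M, R1, C1) - pick(M, R0, C1) - pick(M, R1, C0) + pick(M, R0, C0)
  matrix(box_sum(S) / pmax(box_sum(N), 1), h, w)
}

#' Canopy coverage index of a plot
#'
#' Pre-canopy-closure coverage in [0, 1]: (1) a canopy mask keeps CHM
#' cells at or above the plot's 50th height percentile, refined by local
#' adaptive thresholding of the CHM (mean filter, window `window` px,
#' offset `offset`); (2) the mask is overlaid on the RGB orthomosaic in
#' the (scale ~0.7) plot box; (3) only pixels green in CIELAB space
#' (`a* < a_max`) are kept. CCI = green canopy pixels / total box pixels,
#' so 1 is full coverage.
#'
#' @param chm,rgb aligned [raster_grid]s.
#' @param box half-open pixel box.
#' @param a_max CIELAB a* gate; pixels with a* below it count as green
#'   (default -5).
#' @param window,offset adaptive-threshold window (px, odd) and offset.
#' @return CCI in [0, 1], or `NA` for an empty box.
#' @export
canopy_coverage <- function(chm, rgb, box, a_max = -5, window = 51, offset = 0) {
  hv <- crop_raster(chm, box)$values
  if (!any(!is.na(hv))) return(NA_real_)
  q <- stats::quantile(hv[!is.na(hv)], 0.5, names = FALSE, type = 7)
  q <- q - 1e-7 * (abs(q) + 1) # tolerate float ties from interpolation
  lm <- local_mean(hv, window)
  mask <- !is.na(hv) & hv >= q & hv >= lm + offset
  col <- crop_raster(rgb, box)$values
  a_star <- lab_a_plane(col)
  green <- mask & !is.na(a_star) & a_star < a_max
  sum(green) / length(hv)
}

lab_a_plane <- function(rgb_arr) {
  d <- dim(rgb_arr)
  m <- cbind(as.vector(rgb_arr[, , 1]), as.vector(rgb_arr[, , 2]),
             as.vector(rgb_arr[, , 3])) / 255
  lab <- grDevices::convertColor(m, from = "sRGB", to = "Lab")
  matrix(lab[, 2], d[1], d[2])
}

#' RGB vegetative indices of a plot
#'
#' Per-pixel indices averaged over the (scale ~0.7) plot box; black
#' pixels (R+G+B = 0) and zero-denominator pixels are skipped.
#' Chromatic coordinates r = R/(R+G+B) etc. give
#' `ExG = 2g - r - b` (range [-1, 2]), `ExG_norm = (ExG + 1)/3` in [0, 1],
#' `ExR = 1.4 r - g`, `NVI = (g - r)/(g + r)`;
#' `GLI = (2G - R - B)/(2G + R + B)`, `VARI = (G - R)/(G + R - B)` and
#' `NDYI = (G - B)/(G + B)` are ratio indices on the raw channels. All are
#' invariant to image-wide intensity scaling.
#'
#' @param rgb an 8-bit RGB [raster_grid].
#' @param box half-open pixel box.
#' @return named list: `exg`, `exg_norm`, `exr`, `nvi`, `gli`, `vari`,
#'   `ndyi` (each `NA` if no valid pixel).
#' @export
vegetative_indices <- function(rgb, box) {
  arr <- crop_raster(rgb, box)$values
  R <- as.vector(arr[, , 1]); G <- as.vector(arr[, , 2]); B <- as.vector(arr[, , 3])
  s <- R + G + B
  keep <- s > 0
  R <- R[keep]; G <- G[keep]; B <- B[keep]; s <- s[keep]
  if (!length(s)) {
    na <- NA_real_
    return(list(exg = na, exg_norm = na, exr = na, nvi = na, gli = na, vari = na, ndyi = na))
  }
  r <- R / s; g <- G / s; b <- B / s
  exg <- 2 * g - r - b
  safe_mean <- function(num, den) {
    ok <- den != 0
    if (!any(ok)) NA_real_ else mean(num[ok] / den[ok])
  }
  list(
    exg = mean(exg),
    exg_norm = mean((exg + 1) / 3),
    exr = mean(1.4 * r - g),
    nvi = safe_mean(g - r, g + r),
    gli = safe_mean(2 * G - R - B, 2 * G + R + B),
    vari = safe_mean(G - R, G + R - B),
    ndyi = safe_mean(G - B, G + B)
  )
}

#' Grey-level co-occurrence texture features
#'
#' The plot region is quantized into `levels` equal-width bins, and a
#' symmetric, normalized co-occurrence matrix `P` is accumulated at pixel
#' offset `distance` for each requested angle then averaged.
#' `ASM = sum P^2` (1 iff the quantized region is constant) and
#' `dissimilarity = sum P(i,j) |i - j|` (0 iff all co-occurring pairs are
#' equal).
#'
#' @param grey a greyscale [raster_grid] (e.g. a CHM).
#' @param box half-open pixel box.
#' @param levels quantization levels (default 32).
#' @param distance pixel offset (default 1).
#' @param angles_deg subset of `c(0, 45, 90, 135)` (default all four).
#' @return list with `asm` and `dissimilarity`, both `NA` if the region is
#'   smaller than `distance + 1` in both axes.
#' @export
glcm_features <- function(grey, box, levels = 32, distance = 1,
                          angles_deg = c(0, 45, 90, 135)) {
  stopifnot(distance >= 1, all(angles_deg %in% c(0, 45, 90, 135)))
  v <- crop_raster(grey, box)$values
  h <- nrow(v); w <- ncol(v)
  if (h < distance + 1 && w < distance + 1) {
    return(list(asm = NA_real_, dissimilarity = NA_real_))
  }
  fin <- v[!is.na(v)]
  if (!length(fin)) return(list(asm = NA_real_, dissimilarity = NA_real_))
  rng <- range(fin)
  q <- if (rng[1] == rng[2]) {
    matrix(0L, h, w)
  } else {
    matrix(pmin(as.integer(floor((v - rng[1]) / (rng[2] - rng[1]) * levels)), levels - 1L), h, w)
  }
  q[is.na(v)] <- NA_integer_
  offsets <- list(`0` = c(0, distance), `45` = c(-distance, distance),
                  `90` = c(-distance, 0), `135` = c(-distance, -distance))
  P <- matrix(0, levels, levels)
  n_used <- 0L
  for (a in as.character(angles_deg)) {
    dr <- offsets[[a]][1]; dc <- offsets[[a]][2]
    r_from <- max(1, 1 - dr):min(h, h - dr)
    c_from <- max(1, 1 - dc):min(w, w - dc)
    if (!length(r_from) || !length(c_from)) next
    i <- q[r_from, c_from, drop = FALSE]
    j <- q[r_from + dr, c_from + dc, drop = FALSE]
    ok <- !is.na(i) & !is.na(j)
    if (!any(ok)) next
    tab <- table(factor(i[ok], levels = 0:(levels - 1)),
                 factor(j[ok], levels = 0:(levels - 1)))
    Pa <- tab + t(tab) # symmetric
    P <- P + Pa / sum(Pa)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(list(asm = NA_real_, dissimilarity = NA_real_))
  P <- P / n_used
  dm <- abs(outer(0:(levels - 1), 0:(levels - 1), "-"))
  list(asm = sum(P^2), dissimilarity = sum(P * dm))
}

#' Compute a set of static traits for every plot
#'
#' Applies the per-plot trait operations under trait-specific mask
#' scales: heights at `scale_height`, coverage/colour/texture at
#' `scale_canopy`, seedling counts at `scale_seedling`.
#'
#' @param chm,rgb aligned [raster_grid]s for one date.
#' @param grid an unscaled `plot_grid`.
#' @param das days after sowing of this date.
#' @param traits character vector among `h90`, `h95`, `h50`, `seedlings`,
#'   `cci`, `exg`, `exg_norm`, `exr`, `nvi`, `gli`, `vari`, `ndyi`, `asm`,
#'   `dissimilarity`.
#' @param scale_height,scale_canopy,scale_seedling mask scales.
#' @return data frame of trait records (`plot_id`, `das`, `trait`, `value`).
#' @export
measure_static_traits <- function(chm, rgb, grid, das,
                                  traits = c("h90", "cci", "exg_norm"),
                                  scale_height = 0.3, scale_canopy = 0.7,
                                  scale_seedling = 0.9) {
  g_h <- scale_plot_grid(grid, scale_height)
  g_c <- scale_plot_grid(grid, scale_canopy)
  g_s <- scale_plot_grid(grid, scale_seedling)
  vi_names <- c("exg", "exg_norm", "exr", "nvi", "gli", "vari", "ndyi")
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    box_h <- unlist(g_h[i, c("r0", "c0", "r1", "c1")])
    box_c <- unlist(g_c[i, c("r0", "c0", "r1", "c1")])
    box_s <- unlist(g_s[i, c("r0", "c0", "r1", "c1")])
    vals <- list()
    if ("h90" %in% traits) vals$h90 <- canopy_height(chm, box_h, 0.10)
    if ("h95" %in% traits) vals$h95 <- canopy_height(chm, box_h, 0.05)
    if ("h50" %in% traits) vals$h50 <- canopy_height(chm, box_h, 0.50)
    if ("seedlings" %in% traits) vals$seedlings <- count_seedlings(chm, rgb, box_s)
    if ("cci" %in% traits) vals$cci <- canopy_coverage(chm, rgb, box_c)
    want_vi <- intersect(traits, vi_names)
    if (length(want_vi)) {
      vi <- vegetative_indices(rgb, box_c)
      for (nm in want_vi) vals[[nm]] <- vi[[nm]]
    }
    if (any(c("asm", "dissimilarity") %in% traits)) {
      gl <- glcm_features(chm, box_c)
      if ("asm" %in% traits) vals$asm <- gl$asm
      if ("dissimilarity" %in% traits) vals$dissimilarity <- gl$dissimilarity
    }
    data.frame(plot_id = grid$plot_id[i], das = das,
               trait = names(vals), value = unlist(vals), row.names = NULL)
  })
  do.call(rbind, rows)
}
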