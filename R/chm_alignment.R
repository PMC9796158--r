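#' Fit a four-point perspective transform
#'
#' Exact projective solve mapping the four ROI corners (pixel
#' coordinates, `(col, row)` order) onto the corners of a
#' `target_width x target_height` rectangle: top-left -> (0, 0),
#' top-right -> (w, 0), bottom-right -> (w, h), bottom-left -> (0, h).
#' This is the classical direct linear transform for 4 correspondences
#' (8 unknowns, h33 = 1).
#'
#' @param roi a `roi_quad` in pixel coordinates of the source raster
#'   (x = column, y = row, y increasing downwards), or any 4 x 2 matrix
#'   in canonical corner order.
#' @param target_width,target_height output size in pixels (>= 2).
#' @return a `homography`: 3 x 3 matrix mapping source px -> target px.
#' @export
fit_homography <- function(roi, target_width, target_height) {
  if (target_width < 2 || target_height < 2) stop("target dims must be >= 2", call. = FALSE)
  src <- if (inherits(roi, "roi_quad") || is.data.frame(roi)) cbind(roi$x, roi$y) else as.matrix(roi)
  stopifnot(nrow(src) == 4)
  dst <- rbind(c(0, 0), c(target_width, 0), c(target_width, target_height), c(0, target_height))
  A <- matrix(0, 8, 8); b <- numeric(8)
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
    A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y)
    A[2 * i, ]     <- c(0, 0, 0, x, y, 1, -v * x, -v * y)
    b[2 * i - 1] <- u; b[2 * i] <- v
  }
  dec <- qr(A)
  if (dec$rank < 8) stop("homography fit error: degenerate (collinear) corners", call. = FALSE)
  h <- qr.coef(dec, b)
  H <- matrix(c(h, 1), 3, 3, byrow = TRUE)
  mapped <- apply_homography(H, src)
  resid <- sqrt(rowSums((mapped - dst)^2))
  if (max(resid) > 0.5) stop(sprintf("homography corner residual %.3g px exceeds 0.5 px", max(resid)), call. = FALSE)
  structure(H, class = "homography", corner_residual = max(resid))
}

#' Apply a homography to points
#'
#' @param h a `homography` (3 x 3 matrix).
#' @param pts n x 2 matrix of (x, y) points.
#' @return n x 2 matrix of mapped points.
#' @export
apply_homography <- function(h, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  p <- unclass(h) %*% rbind(t(pts), 1)
  t(p[1:2, , drop = FALSE] / rep(p[3, ], each = 2))
}

#' Warp a raster through a homography
#'
#' Inverse mapping: each target pixel centre is pulled back through
#' `h^-1` and sampled from the source, bilinearly for continuous rasters
#' or nearest-neighbour for masks/label images (which therefore never
#' invent values absent from the input). Pixels mapping outside the
#' source are no-data.
#'
#' @param raster a [raster_grid].
#' @param h a `homography` mapping source px -> target px.
#' @param target_width,target_height output size.
#' @param method `"bilinear"` or `"nearest"`.
#' @return a [raster_grid] of the target size.
#' @export
warp_raster <- function(raster, h, target_width, target_height,
                        method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  hin <- solve(unclass(h))
  d <- dim(raster)
  # target pixel centres, (x=col, y=row) with centre of pixel (r, c) at (c-0.5, r-0.5)
  tx <- rep(seq_len(target_width) - 0.5, each = target_height)
  ty <- rep(seq_len(target_height) - 0.5, target_width)
  src <- apply_homography(structure(hin, class = "homography"), cbind(tx, ty))
  sx <- src[, 1]; sy <- src[, 2]
  sample_plane <- function(vals) {
    out <- rep(NA_real_, length(sx))
    if (method == "nearest") {
      c0 <- floor(sx) + 1; r0 <- floor(sy) + 1
      ok <- c0 >= 1 & c0 <= d[2] & r0 >= 1 & r0 <= d[1]
      out[ok] <- vals[cbind(r0[ok], c0[ok])]
    } else {
      ok <- sx >= 0 & sx <= d[2] & sy >= 0 & sy <= d[1]
      # continuous position in pixel-centre coords, clamped so border
      # pixels interpolate from the outermost cell pair
      fx <- pmin(pmax(sx[ok] - 0.5, 0), d[2] - 1)
      fy <- pmin(pmax(sy[ok] - 0.5, 0), d[1] - 1)
      c0 <- pmin(floor(fx), d[2] - 2); r0 <- pmin(floor(fy), d[1] - 2)
      txf <- fx - c0; tyf <- fy - r0
      i <- cbind(r0 + 1, c0 + 1)
      v00 <- vals[i]; v01 <- vals[cbind(i[, 1], i[, 2] + 1)]
      v10 <- vals[cbind(i[, 1] + 1, i[, 2])]; v11 <- vals[cbind(i[, 1] + 1, i[, 2] + 1)]
      out[ok] <- (1 - tyf) * ((1 - txf) * v00 + txf * v01) + tyf * ((1 - txf) * v10 + txf * v11)
    }
    matrix(out, nrow = target_height, ncol = target_width)
  }
  vals <- if (is_rgb(raster)) {
    arr <- array(NA_real_, c(target_height, target_width, 3))
    for (ch in 1:3) arr[, , ch] <- sample_plane(raster$values[, , ch])
    arr
  } else {
    sample_plane(raster$values)
  }
  raster_grid(vals, res = raster$res, bitdepth = raster$bitdepth)
}

height_palette <- grDevices::colorRampPalette(
  c("#00008B", "#0040FF", "#00A0FF", "#00D080", "#60E000", "#C8E000",
    "#FFD000", "#FF8000", "#FF3000", "#8B0000"))(256)

#' Render a pseudocolour height map
#'
#' Fixed blue-to-red perceptual ramp over 0-150 cm: 0 cm is dark blue,
#' 150 cm and above saturate at dark red, linear (256 levels) in between.
#' The rendering is deterministic: the same CHM always yields identical
#' bytes. No-data cells render black.
#'
#' @param chm a [raster_grid] of heights in cm.
#' @param max_cm saturation height (default 150).
#' @return an 8-bit RGB [raster_grid].
#' @export
render_height_map <- function(chm, max_cm = 150) {
  v <- chm$values
  idx <- pmin(pmax(floor(v / max_cm * 255) + 1, 1), 256)
  col <- grDevices::col2rgb(height_palette)
  arr <- array(0, c(nrow(v), ncol(v), 3))
  ok <- !is.na(idx)
  for (ch in 1:3) {
    plane <- matrix(0, nrow(v), ncol(v))
    plane[ok] <- col[ch, idx[ok]]
    arr[, , ch] <- plane
  }
  raster_grid(arr, res = chm$res, origin = chm$origin, bitdepth = 8L)
}

#' Hue rank of the height palette at a height
#'
#' Helper exposing the colour-ramp index used by [render_height_map()];
#' monotone non-decreasing in height.
#'
#' @param height_cm heights in cm.
#' @param max_cm saturation height.
#' @return integer ramp indices in 1..256.
#' @export
height_ramp_index <- function(height_cm, max_cm = 150) {
  pmin(pmax(floor(height_cm / max_cm * 255) + 1, 1), 256)
}
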