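#' Statistical outlier removal
#'
#' Classical SOR denoising: for each point the mean Euclidean distance to
#' its `k` nearest neighbours is computed; a point is an outlier iff that
#' mean distance exceeds `mean(d) + alpha * sd(d)` taken over the whole
#' cloud.
#'
#' @param cloud a [point_cloud] with more than `k` points.
#' @param k neighbour count (default 8).
#' @param alpha standard-deviation multiplier (default 1).
#' @return list with elements `inliers` and `outliers`, both
#'   [point_cloud]s; their union is the input and they are disjoint.
#' @export
sor_denoise <- function(cloud, k = 8, alpha = 1) {
  if (k < 1 || alpha <= 0) stop("need k >= 1 and alpha > 0", call. = FALSE)
  n <- nrow(cloud)
  if (n <= k) stop(sprintf("cloud has %d points; need more than k = %d", n, k), call. = FALSE)
  nn <- FNN::get.knn(as.matrix(cloud[, c("x", "y", "z")]), k = k)
  d <- rowMeans(nn$nn.dist)
  thresh <- mean(d) + alpha * stats::sd(d)
  out <- d > thresh
  list(inliers = cloud[!out, , drop = FALSE], outliers = cloud[out, , drop = FALSE])
}

#' Ground / aboveground classification by cloth simulation
#'
#' A simplified cloth-simulation filter: the cloud is inverted (z -> -z)
#' and a regular particle grid is dropped onto it from above. Each
#' iteration a particle falls by a fixed gravity displacement, collides
#' with (and sticks to) the highest inverted point in its grid cell, and
#' is then smoothed towards its 4-neighbour mean `rigidness` times (higher
#' rigidness = stiffer cloth spanning plant canopies instead of sagging
#' into them). The settled cloth approximates the ground surface; a point
#' is labelled `ground` iff its vertical distance to the bilinearly
#' interpolated cloth is below `class_threshold`, else `aboveground`.
#'
#' @param cloud a denoised [point_cloud].
#' @param cloth_resolution particle spacing in metres (default 0.2).
#' @param rigidness smoothing passes per iteration, integer grade >= 1
#'   (default 2).
#' @param iterations maximum simulation steps (default 500); the loop also
#'   stops when the largest particle movement falls below 1e-4 m.
#' @param class_threshold ground distance threshold in metres (default 0.05).
#' @return the input cloud with a `label` column (`ground`/`aboveground`).
#' @export
classify_ground <- function(cloud, cloth_resolution = 0.2, rigidness = 2,
                            iterations = 500, class_threshold = 0.05) {
  if (nrow(cloud) == 0) stop("cannot classify an empty cloud", call. = FALSE)
  if (cloth_resolution <= 0) stop("cloth_resolution must be positive", call. = FALSE)
  zi <- -cloud$z # inverted cloud: ground becomes the upper envelope
  xr <- range(cloud$x); yr <- range(cloud$y)
  nx <- max(2L, ceiling(diff(xr) / cloth_resolution) + 1L)
  ny <- max(2L, ceiling(diff(yr) / cloth_resolution) + 1L)
  if (nx < 2 || ny < 2) stop("cloth grid smaller than 2 x 2 particles", call. = FALSE)
  gx <- seq(xr[1], xr[2], length.out = nx)
  gy <- seq(yr[1], yr[2], length.out = ny)
  sx <- if (nx > 1) gx[2] - gx[1] else 1
  sy <- if (ny > 1) gy[2] - gy[1] else 1
  ix <- pmin(nx, pmax(1L, round((cloud$x - xr[1]) / sx) + 1L))
  iy <- pmin(ny, pmax(1L, round((cloud$y - yr[1]) / sy) + 1L))
  hit <- matrix(-Inf, ny, nx)
  cell <- (ix - 1L) * ny + iy
  agg <- tapply(zi, cell, max)
  hit[as.integer(names(agg))] <- agg

  p <- matrix(max(zi) + 1, ny, nx)
  pinned <- matrix(FALSE, ny, nx)
  step <- max(cloth_resolution / 2, 1e-3)
  nb_mean <- function(m) {
    up <- rbind(m[1, , drop = FALSE], m[-nrow(m), , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], m[nrow(m), , drop = FALSE])
    lf <- cbind(m[, 1, drop = FALSE], m[, -ncol(m), drop = FALSE])
    rt <- cbind(m[, -1, drop = FALSE], m[, ncol(m), drop = FALSE])
    (up + dn + lf + rt) / 4
  }
  for (it in seq_len(iterations)) {
    prev <- p
    cand <- ifelse(pinned, p, p - step)       # gravity
    pinned <- pinned | (cand <= hit)          # collision with the point cloud
    p <- pmax(cand, hit)
    for (r in seq_len(rigidness)) {           # internal spring constraints
      sm <- (p + nb_mean(p)) / 2
      p <- ifelse(pinned, p, pmax(sm, hit))
    }
    if (max(abs(p - prev)) < 1e-4) break
  }
  # Relax unpinned particles (cells without collisions, e.g. sparse edges)
  # to the harmonic interpolation of their pinned neighbours, so the cloth
  # carries the settled surface across gaps without the gravity-step sag.
  if (any(!pinned) && any(pinned)) {
    for (it in seq_len(iterations)) {
      prev <- p
      p <- ifelse(pinned, p, pmax(nb_mean(p), hit))
      if (max(abs(p - prev)) < 1e-6) break
    }
  }
  cloth_at <- bilinear_at(gx, gy, p, cloud$x, cloud$y)
  dist <- abs(zi - cloth_at)
  cloud$label <- ifelse(dist < class_threshold, "ground", "aboveground")
  cloud
}

# Duplicate (x, y) locations break the triangulation; average their z.
dedupe_xy <- function(x, y, z) {
  key <- paste(x, y)
  if (!anyDuplicated(key)) return(list(x = x, y = y, z = z))
  keep <- !duplicated(key)
  zm <- tapply(z, key, mean)
  list(x = x[keep], y = y[keep], z = as.numeric(zm[key[keep]]))
}

# Bilinear interpolation of grid values v (rows = y, cols = x) at (px, py).
bilinear_at <- function(gx, gy, v, px, py) {
  fx <- (px - gx[1]) / (gx[2] - gx[1])
  fy <- (py - gy[1]) / (gy[2] - gy[1])
  fx <- pmin(pmax(fx, 0), length(gx) - 1)
  fy <- pmin(pmax(fy, 0), length(gy) - 1)
  x0 <- pmin(floor(fx) + 1, length(gx) - 1); y0 <- pmin(floor(fy) + 1, length(gy) - 1)
  tx <- fx - (x0 - 1); ty <- fy - (y0 - 1)
  v00 <- v[cbind(y0, x0)]; v01 <- v[cbind(y0, x0 + 1)]
  v10 <- v[cbind(y0 + 1, x0)]; v11 <- v[cbind(y0 + 1, x0 + 1)]
  (1 - ty) * ((1 - tx) * v00 + tx * v01) + ty * ((1 - tx) * v10 + tx * v11)
}

#' Rasterize points onto a grid by TIN interpolation
#'
#' Delaunay-triangulates the (x, y) positions and fills each cell centre
#' inside the triangulation with the plane-interpolated z of its
#' containing triangle (exact for points sampled from a plane). Cell
#' centres outside the convex hull are no-data (`NA`).
#'
#' @param points a [point_cloud] (or data frame with x, y, z) with at
#'   least 3 non-collinear points.
#' @param resolution cell size in metres.
#' @param extent optional `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   point bounding box.
#' @return a [raster_grid] of elevations in metres (top row = max y).
#' @export
rasterize_tin <- function(points, resolution, extent = NULL) {
  if (nrow(points) < 3) stop("TIN rasterization needs at least 3 points", call. = FALSE)
  xy <- cbind(points$x, points$y)
  if (qr(sweep(xy, 2, colMeans(xy)))$rank < 2) {
    stop("triangulation error: points are collinear", call. = FALSE)
  }
  if (is.null(extent)) extent <- c(min(points$x), min(points$y), max(points$x), max(points$y))
  ncol <- max(1L, ceiling((extent[3] - extent[1]) / resolution))
  nrow <- max(1L, ceiling((extent[4] - extent[2]) / resolution))
  xyz <- dedupe_xy(points$x, points$y, points$z)
  mesh <- interp::tri.mesh(xyz$x, xyz$y)
  tri <- interp::triangles(mesh)[, 1:3, drop = FALSE]
  vals <- .tin_rasterize(tri, xyz$x, xyz$y, xyz$z, nrow, ncol,
                         extent[1], extent[4], resolution)
  raster_grid(vals, res = resolution, origin = c(extent[1], extent[4]))
}

#' Build a canopy height model
#'
#' Cell-wise `max(0, surface - ground) * 100`: canopy height in
#' centimetres, clipped at zero so vertical noise never yields negative
#' heights. No-data in either input propagates.
#'
#' @param ground,surface aligned elevation [raster_grid]s in metres.
#' @return a [raster_grid] of heights in cm.
#' @export
build_chm <- function(ground, surface) {
  if (!rasters_aligned(ground, surface)) {
    stop("ground and surface rasters are misaligned (shape/res/origin differ)", call. = FALSE)
  }
  chm <- pmax(surface$values - ground$values, 0) * 100
  raster_grid(chm, res = ground$res, origin = ground$origin)
}

#' Least-squares plane fit
#'
#' @param reference data frame with `x`, `y`, `z` of at least 3
#'   non-collinear reference points (ground-labelled points or ROI corner
#'   elevations).
#' @return named vector `c(alpha, beta, gamma)` of `z = alpha x + beta y + gamma`.
#' @export
fit_plane <- function(reference) {
  if (nrow(reference) < 3) stop("plane fit needs at least 3 reference points", call. = FALSE)
  A <- cbind(reference$x, reference$y, 1)
  dec <- qr(A)
  if (dec$rank < 3) stop("plane fit error: reference points are collinear", call. = FALSE)
  coef <- qr.coef(dec, reference$z)
  stats::setNames(coef, c("alpha", "beta", "gamma"))
}

#' Remove the field-level terrain slope
#'
#' Fits `z = alpha x + beta y + gamma` to the reference elevations and
#' subtracts the plane value from every point (cloud) or cell (raster).
#' Applying the correction twice is the same as once (the refit plane of
#' corrected references is zero within 1e-9).
#'
#' @param obj a [point_cloud] or [raster_grid] of elevations in metres.
#' @param reference data frame with `x`, `y`, `z` reference elevations.
#' @return list with `corrected` (same type as `obj`) and `plane`
#'   (`c(alpha, beta, gamma)`).
#' @export
remove_slope <- function(obj, reference) {
  plane <- fit_plane(reference)
  if (inherits(obj, "raster_grid")) {
    d <- dim(obj)
    cx <- obj$origin[1] + (seq_len(d[2]) - 0.5) * obj$res
    cy <- obj$origin[2] - (seq_len(d[1]) - 0.5) * obj$res
    planev <- outer(cy, cx, function(y, x) plane[1] * x + plane[2] * y + plane[3])
    out <- raster_grid(obj$values - planev, res = obj$res, origin = obj$origin,
                       bitdepth = obj$bitdepth)
  } else {
    out <- obj
    out$z <- obj$z - (plane[1] * obj$x + plane[2] * obj$y + plane[3])
  }
  list(corrected = out, plane = plane)
}
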