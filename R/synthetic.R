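# Synthetic field trials with known ground truth. The generators stand in
# for the photogrammetry products (point cloud + orthomosaic) of a real
# gridded paddy trial: a sloped ground plane carrying a grid of plant
# plots, water-coloured inter-plot gaps, soil clods and voluntary-plant
# style distractors, and Gaussian-shaped trait time series.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Colour book (8-bit RGB). Water is a muted grey-blue whose CIELAB a* sits
# above the green gate, so it never counts as vegetation.
SYN_COL <- list(plant = c(60, 160, 60), soil = c(125, 100, 70),
                water = c(95, 115, 150), clod = c(140, 100, 60))

#' Define a synthetic field trial with known truth
#'
#' The field is a `n_rows x n_cols` grid of rectangular plots
#' (`plot_w x plot_h` m, separated by water-filled gaps) on a sloped
#' ground plane `z = alpha x + beta y + gamma`. Each plot carries a plant
#' canopy whose surface is a plateau dome: full canopy height over the
#' central 60% of the plot, falling to zero at the plot edge along a
#' Beta(4, 2) profile, so the height truth inside centrally scaled
#' sampling boxes (scale <= 0.6) is exactly the nominal height. Plot
#' canopy heights, coverage fractions and seedling centres are drawn once
#' from the seed and recorded as truth.
#'
#' @param n_rows,n_cols trial grid (default 4 x 5).
#' @param seed integer seed; the same seed reproduces the truth and every
#'   generated product exactly.
#' @param plane `c(alpha, beta, gamma)` terrain slope in m/m and m
#'   (default `c(0.02, 0.01, 3)`).
#' @param height_range_cm per-plot canopy height range to draw from
#'   (default 60-130 cm, the span of paddy rice canopies).
#' @param coverage_range per-plot canopy coverage fraction range.
#' @param heights_cm,coverage optional explicit per-plot values (length 1
#'   or `n_rows * n_cols`, row-major) overriding the random draws; used
#'   for multi-date designs where heights follow a growth curve.
#' @param n_seedlings seedlings per plot (default 18, a typical
#'   transplanting design).
#' @param plot_w,plot_h,gap,margin field geometry in metres.
#' @return a `field_truth` list: `layout`, `plane`, `extent`
#'   (xmin, ymin, xmax, ymax), `plots` (world boxes + per-plot truth),
#'   `roi` (corner table of the plot region), `seed`, geometry.
#' @export
field_truth <- function(n_rows = 4, n_cols = 5, seed = 1,
                        plane = c(0.02, 0.01, 3),
                        height_range_cm = c(60, 130),
                        coverage_range = c(0.3, 0.9),
                        heights_cm = NULL, coverage = NULL,
                        n_seedlings = 18,
                        plot_w = 2.0, plot_h = 1.2, gap = 0.4, margin = 0.8) {
  layout <- trial_layout(n_rows, n_cols)
  pitch_x <- plot_w + gap; pitch_y <- plot_h + gap
  field_w <- 2 * margin + n_cols * pitch_x - gap
  field_h <- 2 * margin + n_rows * pitch_y - gap
  plots <- as.data.frame(layout)
  # world frame: y up; layout row 1 is the top (max y) row
  plots$x0 <- margin + (plots$col - 1) * pitch_x
  plots$x1 <- plots$x0 + plot_w
  plots$y1 <- field_h - margin - (plots$row - 1) * pitch_y
  plots$y0 <- plots$y1 - plot_h
  with_seed(seed, {
    plots$height_cm <- if (is.null(heights_cm)) {
      stats::runif(nrow(plots), height_range_cm[1], height_range_cm[2])
    } else rep(heights_cm, length.out = nrow(plots))
    plots$coverage <- if (is.null(coverage)) {
      stats::runif(nrow(plots), coverage_range[1], coverage_range[2])
    } else rep(coverage, length.out = nrow(plots))
    seedlings <- lapply(seq_len(nrow(plots)), function(i) {
      seedling_centres(n_seedlings, plots$x0[i], plots$y0[i], plot_w, plot_h)
    })
  })
  roi <- roi_quad(data.frame(
    name = c("tl", "tr", "br", "bl"),
    x = c(margin, field_w - margin, field_w - margin, margin),
    y = c(field_h - margin, field_h - margin, margin, margin)))
  structure(list(layout = layout, plane = plane, plots = plots,
                 seedlings = seedlings, roi = roi,
                 extent = c(0, 0, field_w, field_h),
                 plot_w = plot_w, plot_h = plot_h, gap = gap, margin = margin,
                 seed = seed),
            class = "field_truth")
}

# Jittered-grid seedling positions with guaranteed pairwise separation.
seedling_centres <- function(n, x0, y0, w, h) {
  if (n == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  nc <- ceiling(sqrt(n * w / h)); nr <- ceiling(n / nc)
  sx <- w / (nc + 1); sy <- h / (nr + 1)
  g <- expand.grid(i = seq_len(nc), j = seq_len(nr))[seq_len(n), ]
  jit <- min(sx, sy) * 0.15
  data.frame(x = x0 + g$i * sx + stats::runif(n, -jit, jit),
             y = y0 + g$j * sy + stats::runif(n, -jit, jit))
}

# Plateau dome: 1 on the central 75% (max-norm radius), Beta(4,2)-CDF
# falloff to 0 at the plot edge. The plateau covers every sampling-box
# scale up to 0.75, so centrally scaled height and coverage statistics
# see a flat canopy whose truth is the nominal plot height.
dome_factor <- function(u) {
  t <- pmin(pmax((1 - u) / 0.25, 0), 1)
  stats::pbeta(t, 4, 2)
}

plot_dome_height <- function(truth, i, x, y) {
  p <- truth$plots[i, ]
  cx <- (p$x0 + p$x1) / 2; cy <- (p$y0 + p$y1) / 2
  u <- pmax(abs(x - cx) / ((p$x1 - p$x0) / 2), abs(y - cy) / ((p$y1 - p$y0) / 2))
  p$height_cm / 100 * dome_factor(u)
}

plane_z <- function(plane, x, y) plane[1] * x + plane[2] * y + plane[3]

#' Generate the synthetic field point cloud
#'
#' Ground points are sampled uniformly over the field on the slope plane
#' (plus vertical Gaussian noise); plant points are sampled inside each
#' plot box on the plateau-dome canopy surface; outlier points are
#' injected at +/- 5-100 m vertical offsets at the stated fraction.
#' Colours: plants green-dominant, soil brown, inter-plot gaps
#' water-blue. A pure function of (truth, arguments): the same seed gives
#' an identical cloud.
#'
#' @param truth a [field_truth()].
#' @param points_per_plot plant points per plot (default 500).
#' @param ground_density ground points per square metre (default 50).
#' @param sigma_z vertical noise SD in metres (default 0).
#' @param outlier_frac fraction of extra outlier points (default 0).
#' @return a [point_cloud] with colours.
#' @export
generate_field_cloud <- function(truth, points_per_plot = 500,
                                 ground_density = 50, sigma_z = 0,
                                 outlier_frac = 0) {
  ext <- truth$extent
  with_seed(truth$seed + 1L, {
    n_ground <- ceiling((ext[3] - ext[1]) * (ext[4] - ext[2]) * ground_density)
    gx <- stats::runif(n_ground, ext[1], ext[3])
    gy <- stats::runif(n_ground, ext[2], ext[4])
    gz <- plane_z(truth$plane, gx, gy) + stats::rnorm(n_ground, 0, sigma_z)
    in_plot <- rep(FALSE, n_ground)
    for (i in seq_len(nrow(truth$plots))) {
      p <- truth$plots[i, ]
      in_plot <- in_plot | (gx >= p$x0 & gx <= p$x1 & gy >= p$y0 & gy <= p$y1)
    }
    gcol <- matrix(rep(SYN_COL$water, each = n_ground), n_ground)
    gcol[in_plot, ] <- matrix(rep(SYN_COL$soil, each = sum(in_plot)), sum(in_plot))
    parts_xyz <- list(cbind(gx, gy, gz))
    parts_col <- list(gcol)
    for (i in seq_len(nrow(truth$plots))) {
      p <- truth$plots[i, ]
      px <- stats::runif(points_per_plot, p$x0, p$x1)
      py <- stats::runif(points_per_plot, p$y0, p$y1)
      pz <- plane_z(truth$plane, px, py) + plot_dome_height(truth, i, px, py) +
        stats::rnorm(points_per_plot, 0, sigma_z)
      parts_xyz[[i + 1]] <- cbind(px, py, pz)
      parts_col[[i + 1]] <- matrix(rep(SYN_COL$plant, each = points_per_plot), points_per_plot)
    }
    xyz <- do.call(rbind, parts_xyz)
    cols <- do.call(rbind, parts_col)
    n_out <- round(outlier_frac * nrow(xyz))
    if (n_out > 0) {
      ox <- stats::runif(n_out, ext[1], ext[3])
      oy <- stats::runif(n_out, ext[2], ext[4])
      oz <- plane_z(truth$plane, ox, oy) +
        sample(c(-1, 1), n_out, replace = TRUE) * stats::runif(n_out, 5, 100)
      xyz <- rbind(xyz, cbind(ox, oy, oz))
      cols <- rbind(cols, matrix(rep(c(200, 200, 200), each = n_out), n_out))
    }
    point_cloud(xyz, colours = cols)
  })
}

#' Generate the synthetic orthomosaic
#'
#' Paints the field at `px_per_m` pixels per metre, top row = max y.
#' In `"canopy"` mode every plot pixel is green with probability equal to
#' the plot's coverage fraction (soil otherwise); in `"seedling"` mode
#' plots show green disks of radius `disk_px` at the truth's seedling
#' centres, with `n_clods` brown clods of the same size as distractors.
#' Gaps are water-coloured with speckle noise.
#'
#' @param truth a [field_truth()].
#' @param px_per_m pixels per metre (>= 20; default 40).
#' @param mode `"canopy"` or `"seedling"`.
#' @param disk_px seedling disk radius in px (default 3).
#' @param n_clods distractor clods per plot in seedling mode (default 0).
#' @return an 8-bit RGB [raster_grid]; clod centres, when any, are
#'   attached as attribute `clods`.
#' @export
generate_orthomosaic <- function(truth, px_per_m = 40,
                                 mode = c("canopy", "seedling"),
                                 disk_px = 3, n_clods = 0) {
  mode <- match.arg(mode)
  if (px_per_m < 20) stop("px_per_m must be at least 20", call. = FALSE)
  ext <- truth$extent
  w <- round((ext[3] - ext[1]) * px_per_m)
  h <- round((ext[4] - ext[2]) * px_per_m)
  world_to_px <- function(x, y) cbind(col = x * px_per_m, row = h - y * px_per_m)
  with_seed(truth$seed + 2L, {
    base <- matrix(stats::runif(h * w, -8, 8), h, w) # speckle
    arr <- array(0, c(h, w, 3))
    for (ch in 1:3) arr[, , ch] <- SYN_COL$water[ch] + base
    clod_log <- list()
    for (i in seq_len(nrow(truth$plots))) {
      p <- truth$plots[i, ]
      c0 <- max(1, floor(p$x0 * px_per_m) + 1); c1 <- min(w, ceiling(p$x1 * px_per_m))
      r1 <- min(h, ceiling(h - p$y0 * px_per_m)); r0 <- max(1, floor(h - p$y1 * px_per_m) + 1)
      rows <- r0:r1; cols <- c0:c1
      npx <- length(rows) * length(cols)
      if (mode == "canopy") {
        green <- matrix(stats::runif(npx) < p$coverage, length(rows), length(cols))
        for (ch in 1:3) {
          plane <- arr[rows, cols, ch]
          plane[green] <- SYN_COL$plant[ch] + base[rows, cols][green]
          plane[!green] <- SYN_COL$soil[ch] + base[rows, cols][!green]
          arr[rows, cols, ch] <- plane
        }
      } else {
        for (ch in 1:3) arr[rows, cols, ch] <- SYN_COL$soil[ch] + base[rows, cols]
        cent <- world_to_px(truth$seedlings[[i]]$x, truth$seedlings[[i]]$y)
        arr <- paint_disks(arr, cent, disk_px, SYN_COL$plant)
        if (n_clods > 0) {
          cl <- clod_centres(truth, i, n_clods, disk_px / px_per_m)
          arr <- paint_disks(arr, world_to_px(cl$x, cl$y), disk_px, SYN_COL$clod)
          clod_log[[length(clod_log) + 1]] <- cl
        }
      }
    }
    out <- raster_grid(pmin(pmax(round(arr), 0), 255), res = 1 / px_per_m,
                       origin = c(ext[1], ext[4]), bitdepth = 8L)
    if (length(clod_log)) attr(out, "clods") <- do.call(rbind, clod_log)
    out
  })
}

# Clods sit along the plot mid-line between seedling grid rows, away from
# every seedling disk.
clod_centres <- function(truth, i, n, radius_m) {
  p <- truth$plots[i, ]
  sdl <- truth$seedlings[[i]]
  cand_x <- seq(p$x0 + 4 * radius_m, p$x1 - 4 * radius_m, length.out = n + 2)[2:(n + 1)]
  cand <- data.frame(x = cand_x, y = rep((p$y0 + p$y1) / 2, n))
  for (k in seq_len(n)) {
    repeat {
      d <- sqrt((sdl$x - cand$x[k])^2 + (sdl$y - cand$y[k])^2)
      if (min(d) > 3.5 * radius_m) break
      cand$y[k] <- cand$y[k] + 2.5 * radius_m
    }
  }
  cand
}

paint_disks <- function(arr, centres_px, radius, colour) {
  h <- dim(arr)[1]; w <- dim(arr)[2]
  for (k in seq_len(nrow(centres_px))) {
    cc <- centres_px[k, 1]; rc <- centres_px[k, 2]
    rs <- max(1, floor(rc - radius)):min(h, ceiling(rc + radius))
    cs <- max(1, floor(cc - radius)):min(w, ceiling(cc + radius))
    for (r in rs) for (cl in cs) {
      if ((r - 0.5 - rc)^2 + (cl - 0.5 - cc)^2 <= radius^2) {
        arr[r, cl, ] <- colour
      }
    }
  }
  arr
}

#' Synthetic CHM matching an orthomosaic scene
#'
#' Renders the truth's canopy (or seedling disks and clods) as a height
#' raster in cm on the same pixel grid as [generate_orthomosaic()],
#' bypassing the point-cloud pipeline. Used to test the trait operations
#' in isolation with an exactly known scene.
#'
#' @param truth a [field_truth()].
#' @param px_per_m pixels per metre.
#' @param mode `"canopy"` (plateau domes at each plot's height) or
#'   `"seedling"` (flat disks of `seedling_height_cm` at seedling and
#'   clod positions).
#' @param ortho the orthomosaic (required in seedling mode with clods, to
#'   reuse its clod positions).
#' @param disk_px,seedling_height_cm seedling-mode geometry.
#' @return a greyscale [raster_grid] of heights in cm.
#' @export
generate_truth_chm <- function(truth, px_per_m = 40,
                               mode = c("canopy", "seedling"),
                               ortho = NULL, disk_px = 3,
                               seedling_height_cm = 10) {
  mode <- match.arg(mode)
  ext <- truth$extent
  w <- round((ext[3] - ext[1]) * px_per_m)
  h <- round((ext[4] - ext[2]) * px_per_m)
  xs <- ext[1] + (seq_len(w) - 0.5) / px_per_m
  ys <- ext[4] - (seq_len(h) - 0.5) / px_per_m
  v <- matrix(0, h, w)
  if (mode == "canopy") {
    for (i in seq_len(nrow(truth$plots))) {
      p <- truth$plots[i, ]
      cols <- which(xs >= p$x0 & xs <= p$x1)
      rows <- which(ys >= p$y0 & ys <= p$y1)
      if (!length(cols) || !length(rows)) next
      gx <- rep(xs[cols], each = length(rows))
      gy <- rep(ys[rows], length(cols))
      v[rows, cols] <- matrix(plot_dome_height(truth, i, gx, gy) * 100,
                              length(rows), length(cols))
    }
  } else {
    centres <- do.call(rbind, lapply(truth$seedlings, function(s) cbind(s$x, s$y)))
    if (!is.null(ortho) && !is.null(attr(ortho, "clods"))) {
      cl <- attr(ortho, "clods")
      centres <- rbind(centres, cbind(cl$x, cl$y))
    }
    px <- cbind(centres[, 1] * px_per_m, h - centres[, 2] * px_per_m)
    zero <- array(0, c(h, w, 3))
    painted <- paint_disks(zero, px, disk_px, rep(seedling_height_cm, 3))
    v <- painted[, , 1]
  }
  raster_grid(v, res = 1 / px_per_m, origin = c(ext[1], ext[4]))
}

#' Generate Gaussian trait time series with known parameters
#'
#' `value = d + a exp(-(t - b)^2 / (2 c^2)) + N(0, sigma)`, seeded. The
#' default sample days are eight flights relatively evenly spaced between
#' 10 and 115 days after sowing.
#'
#' @param params data frame with columns `plot_id`, `a`, `b`, `c`, `d`.
#' @param days sample days (default `c(10, 25, 40, 55, 70, 85, 100, 115)`).
#' @param sigma value noise SD (default 0).
#' @param seed integer seed.
#' @param trait trait name for the records (default `"h90"`).
#' @return trait records data frame (`plot_id`, `das`, `trait`, `value`).
#' @export
generate_growth_series <- function(params, days = c(10, 25, 40, 55, 70, 85, 100, 115),
                                   sigma = 0, seed = 1, trait = "h90") {
  if (length(days) < 5) stop("need at least 5 sample days", call. = FALSE)
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(params)), function(i) {
      p <- params[i, ]
      v <- p$d + p$a * exp(-(days - p$b)^2 / (2 * p$c^2)) + stats::rnorm(length(days), 0, sigma)
      data.frame(plot_id = p$plot_id, das = days, trait = trait, value = v)
    })
    do.call(rbind, rows)
  })
}

#' Write a full synthetic season to disk
#'
#' Builds a multi-date trial: per-plot canopy heights follow an offset
#' Gaussian growth curve (parameters drawn once per plot from the seed),
#' and each flight date gets its own point cloud and orthomosaic. A
#' ready-to-run season config file is written alongside the ROI and
#' layout tables, with the reference date set to the mid-season flight.
#'
#' @param dir output directory.
#' @param n_rows,n_cols trial grid.
#' @param seed integer seed.
#' @param days flight days after sowing (default eight flights, 10-115).
#' @param a_range,b_range,c_range growth-curve parameter ranges per plot:
#'   amplitude (cm), peak day (DAS), width (days).
#' @param sigma_z,outlier_frac per-date cloud noise.
#' @param px_per_m orthomosaic resolution.
#' @param ground_density,points_per_plot cloud densities.
#' @return list with `config` (path), `truth` (the reference
#'   [field_truth()]) and `params` (per-plot growth parameters),
#'   invisibly.
#' @export
write_synthetic_season <- function(dir, n_rows = 4, n_cols = 5, seed = 1,
                                   days = c(10, 25, 40, 55, 70, 85, 100, 115),
                                   a_range = c(70, 120), b_range = c(80, 100),
                                   c_range = c(15, 25),
                                   sigma_z = 0, outlier_frac = 0,
                                   px_per_m = 40, ground_density = 50,
                                   points_per_plot = 500) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- field_truth(n_rows, n_cols, seed = seed)
  n <- nrow(base$plots)
  params <- with_seed(seed + 10L, data.frame(
    plot_id = base$plots$plot_id,
    a = stats::runif(n, a_range[1], a_range[2]),
    b = stats::runif(n, b_range[1], b_range[2]),
    c = stats::runif(n, c_range[1], c_range[2]),
    d = 0))
  lines <- c(sprintf("roi = roi.csv"), sprintf("layout = layout.csv"),
             "out_dir = out", sprintf("reference_date = %d", which.min(abs(days - 85))))
  for (k in seq_along(days)) {
    h_k <- params$a * exp(-(days[k] - params$b)^2 / (2 * params$c^2)) + params$d
    tr_k <- field_truth(n_rows, n_cols, seed = seed, heights_cm = h_k,
                        coverage = base$plots$coverage)
    cloud <- generate_field_cloud(tr_k, points_per_plot = points_per_plot,
                                  ground_density = ground_density,
                                  sigma_z = sigma_z, outlier_frac = outlier_frac)
    write_point_cloud(cloud, file.path(dir, sprintf("cloud_das%03d.xyz", days[k])))
    write_raster(generate_orthomosaic(tr_k, px_per_m),
                 file.path(dir, sprintf("ortho_das%03d.png", days[k])))
    lines <- c(lines,
               sprintf("date%d.cloud = cloud_das%03d.xyz", k, days[k]),
               sprintf("date%d.ortho = ortho_das%03d.png", k, days[k]),
               sprintf("date%d.das = %d", k, days[k]))
  }
  roi <- as.data.frame(base$roi)
  roi$name <- rownames(roi)
  utils::write.csv(roi[, c("name", "x", "y")], file.path(dir, "roi.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(base$layout), file.path(dir, "layout.csv"),
                   row.names = FALSE, quote = FALSE)
  cfg <- file.path(dir, "season.cfg")
  writeLines(lines, cfg)
  invisible(list(config = cfg, truth = base, params = params))
}

#' Write a full synthetic field fixture to disk
#'
#' Emits the point cloud (xyz text), orthomosaic (PNG), ROI corner CSV,
#' layout CSV and the truth as JSON.
#'
#' @param truth a [field_truth()].
#' @param dir output directory (created if missing).
#' @param ... passed to [generate_field_cloud()].
#' @param px_per_m orthomosaic resolution.
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic_field <- function(truth, dir, ..., px_per_m = 40) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cloud = file.path(dir, "cloud.xyz"),
             ortho = file.path(dir, "orthomosaic.png"),
             roi = file.path(dir, "roi.csv"),
             layout = file.path(dir, "layout.csv"),
             truth = file.path(dir, "truth.json"))
  write_point_cloud(generate_field_cloud(truth, ...), paths["cloud"])
  write_raster(generate_orthomosaic(truth, px_per_m), paths["ortho"])
  roi <- as.data.frame(truth$roi)
  roi$name <- rownames(roi)
  utils::write.csv(roi[, c("name", "x", "y")], paths["roi"], row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(truth$layout), paths["layout"], row.names = FALSE, quote = FALSE)
  tr <- unclass(truth)
  tr$layout <- as.data.frame(tr$layout)
  tr$roi <- as.data.frame(tr$roi)
  jsonlite::write_json(tr, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
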