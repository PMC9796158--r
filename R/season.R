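# Season batch pipeline: the headless equivalent of the platform's batch
# workflow. One reference date defines the plot masks; every date is
# processed against them; static traits are merged and dynamic phenotypes
# fitted at the end.

#' Read a season configuration file
#'
#' Flat `key = value` text with `#` comments. Required keys: `roi`,
#' `layout`, `out_dir`, and per date `date<i>.cloud`, `date<i>.ortho`,
#' `date<i>.das` (`i` = 1, 2, ...; DAS strictly increasing). Optional
#' keys override algorithm defaults: `reference_date` (index, default 1),
#' `px_per_m` (orthomosaic resolution, default 40; the world frame is
#' anchored at the orthomosaic's bottom-left corner, so ROI coordinates
#' are metres in that frame), `chm_res` (m, default 0.05), `traits` (comma list), `scale_height`,
#' `scale_canopy`, `scale_seedling`, `sor_k`, `sor_alpha`, `cloth_res`,
#' `rigidness`, `class_threshold`, `vote_frac`, `angle_tol`,
#' `manual_h` / `manual_v` (comma lists of px positions).
#'
#' @param path config file.
#' @return a `season_config` list.
#' @export
read_season_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- lines[grepl("=", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(p) paste(p[-1], collapse = "="), ""))
  conf <- stats::setNames(as.list(vals), keys)
  season_config(conf, base = dirname(path))
}

season_config <- function(conf, base = ".") {
  getv <- function(key, default = NULL) if (!is.null(conf[[key]])) conf[[key]] else default
  num <- function(key, default) as.numeric(getv(key, default))
  dates <- list()
  i <- 1
  while (!is.null(conf[[sprintf("date%d.cloud", i)]])) {
    dates[[i]] <- list(cloud = file.path(base, conf[[sprintf("date%d.cloud", i)]]),
                       ortho = file.path(base, conf[[sprintf("date%d.ortho", i)]]),
                       das = as.numeric(conf[[sprintf("date%d.das", i)]]))
    i <- i + 1
  }
  if (!length(dates)) stop("season config lists no dates", call. = FALSE)
  das <- vapply(dates, `[[`, 0, "das")
  if (is.unsorted(das, strictly = TRUE)) stop("date DAS values must be strictly increasing", call. = FALSE)
  for (key in c("roi", "layout")) {
    if (is.null(conf[[key]])) stop(sprintf("season config needs key '%s'", key), call. = FALSE)
  }
  split_num <- function(key) {
    v <- getv(key)
    if (is.null(v) || !nzchar(v)) NULL else as.numeric(strsplit(v, ",")[[1]])
  }
  structure(list(
    dates = dates,
    roi = file.path(base, conf$roi),
    layout = file.path(base, conf$layout),
    out_dir = file.path(base, getv("out_dir", "out")),
    reference_date = as.integer(num("reference_date", 1)),
    px_per_m = num("px_per_m", 40),
    chm_res = num("chm_res", 0.05),
    traits = trimws(strsplit(getv("traits", "h90,cci,exg_norm"), ",")[[1]]),
    scale_height = num("scale_height", 0.3),
    scale_canopy = num("scale_canopy", 0.7),
    scale_seedling = num("scale_seedling", 0.9),
    sor_k = as.integer(num("sor_k", 8)), sor_alpha = num("sor_alpha", 1),
    cloth_res = num("cloth_res", 0.2), rigidness = as.integer(num("rigidness", 2)),
    class_threshold = num("class_threshold", 0.05),
    vote_frac = num("vote_frac", 0.8), angle_tol = num("angle_tol", 5),
    manual_h = split_num("manual_h"), manual_v = split_num("manual_v")
  ), class = "season_config")
}

#' Build the aligned CHM for one date
#'
#' Cloud to aligned canopy height model: SOR denoise, cloth-simulation
#' ground classification, per-class TIN rasterization (the surface model
#' falls back to the ground elevation where no plant evidence exists),
#' CHM differencing, residual slope-plane removal against the
#' ground-labelled points, and perspective alignment onto the ROI
#' rectangle of the orthomosaic pixel frame.
#'
#' @param cloud a [point_cloud].
#' @param roi `roi_quad` in world metres.
#' @param ortho the date's orthomosaic [raster_grid] (defines the target
#'   pixel frame); `NULL` aligns at `1/chm_res` px per metre instead.
#' @param config optional `season_config` overriding the algorithm
#'   defaults below.
#' @param chm_res CHM cell size in metres.
#' @param sor_k,sor_alpha SOR parameters.
#' @param cloth_res,rigidness,class_threshold cloth-filter parameters.
#' @return list: `chm` (aligned, cm), `ortho_crop` (aligned RGB or NULL),
#'   `homography`, `plane`, `ground_frac`.
#' @export
build_aligned_chm <- function(cloud, roi, ortho = NULL, config = NULL,
                              chm_res = 0.05, sor_k = 8, sor_alpha = 1,
                              cloth_res = 0.2, rigidness = 2,
                              class_threshold = 0.05) {
  if (is.null(config)) {
    config <- list(chm_res = chm_res, sor_k = sor_k, sor_alpha = sor_alpha,
                   cloth_res = cloth_res, rigidness = rigidness,
                   class_threshold = class_threshold)
  }
  den <- sor_denoise(cloud, k = config$sor_k, alpha = config$sor_alpha)
  lab <- classify_ground(den$inliers, cloth_resolution = config$cloth_res,
                         rigidness = config$rigidness,
                         class_threshold = config$class_threshold)
  gnd <- lab[lab$label == "ground", ]
  abv <- lab[lab$label == "aboveground", ]
  ext <- c(min(lab$x), min(lab$y), max(lab$x), max(lab$y))
  ground_r <- rasterize_tin(gnd, config$chm_res, ext)
  surface_r <- if (nrow(abv) >= 3) rasterize_tin(abv, config$chm_res, ext) else ground_r
  # the aboveground TIN spans the convex hull, bridging bare inter-plot
  # gaps; only keep it where aboveground points actually fall (occupancy
  # dilated by one cell), and use the ground surface elsewhere
  sv <- surface_r$values
  if (nrow(abv) >= 3) sv[!cell_occupancy(abv, ground_r, dilate = 1)] <- NA
  surface_r$values <- pmax(ifelse(is.na(sv), ground_r$values, sv), ground_r$values)
  # residual field-level slope: the differencing removes terrain cell-wise,
  # so the plane fitted to corrected ground points is ~0; kept as an
  # explicit health step and for clouds with biased ground sampling
  chm <- build_chm(ground_r, surface_r)
  slope <- remove_slope(gnd, reference = gnd)
  # map world ROI into CHM pixel coordinates
  roi_px <- data.frame(x = (roi$x - ext[1]) / config$chm_res,
                       y = (ext[4] - roi$y) / config$chm_res)
  if (!is.null(ortho)) {
    px_per_m <- 1 / ortho$res
    o_px <- data.frame(x = (roi$x - ortho$origin[1]) * px_per_m,
                       y = (ortho$origin[2] - roi$y) * px_per_m)
    tw <- round(o_px$x[2] - o_px$x[1]); th <- round(o_px$y[4] - o_px$y[1])
    crop_box <- c(round(o_px$y[1]), round(o_px$x[1]),
                  round(o_px$y[1]) + th, round(o_px$x[1]) + tw)
    ortho_crop <- crop_raster(ortho, crop_box)
  } else {
    tw <- round(max(roi_px$x) - min(roi_px$x)); th <- round(max(roi_px$y) - min(roi_px$y))
    ortho_crop <- NULL
  }
  h <- fit_homography(roi_px, tw, th)
  aligned <- warp_raster(chm, h, tw, th)
  list(chm = aligned, ortho_crop = ortho_crop, homography = h,
       plane = slope$plane, ground_frac = nrow(gnd) / nrow(lab))
}

#' Run a full season batch
#'
#' Processes every date of a [read_season_config()] season: builds the
#' aligned CHM, segments plots on the reference date (the resulting masks
#' benchmark all dates), measures the configured static traits per plot
#' and date, writes per-date and merged trait CSVs, fits dynamic
#' phenotypes per plot, and renders a per-date pseudocolour height map.
#' Dates whose inputs are missing or fail are logged and skipped; a
#' segmentation failure on the reference date aborts.
#'
#' @param config a `season_config` (or path to one).
#' @return invisibly, a list with `trait_table`, `dynamics`, `plots`
#'   (the reference `plot_grid`) and `log` (data frame of per-stage
#'   timings); files are written under `config$out_dir`.
#' @export
run_season <- function(config) {
  if (is.character(config)) config <- read_season_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  roi <- read_roi(config$roi)
  layout <- read_layout(config$layout)
  log <- list()
  note <- function(stage, date, n, t0) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, date = date, plots = n,
                                          seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  }
  # reference date first: it defines the plot masks
  ref <- config$reference_date
  order_idx <- c(ref, setdiff(seq_along(config$dates), ref))
  plots <- NULL
  records <- list()
  for (i in order_idx) {
    d <- config$dates[[i]]
    t0 <- Sys.time()
    if (!file.exists(d$cloud) || !file.exists(d$ortho)) {
      if (i == ref) stop(sprintf("reference date %d inputs missing: %s", i, d$cloud), call. = FALSE)
      warning(sprintf("date %d (DAS %g) inputs missing; skipped", i, d$das), call. = FALSE)
      note("skipped", i, 0, t0)
      next
    }
    res <- tryCatch({
      cloud <- read_point_cloud(d$cloud)
      ortho <- read_raster(d$ortho)
      # PNG carries no georeferencing: the config's px_per_m and the
      # bottom-left-anchored world frame supply it
      ortho$res <- 1 / config$px_per_m
      ortho$origin <- c(0, dim(ortho)[1] / config$px_per_m)
      al <- build_aligned_chm(cloud, roi, ortho, config)
      if (i == ref) {
        plots <- segment_plots(al$chm, layout, angle_tol_deg = config$angle_tol,
                                vote_frac = config$vote_frac,
                                manual_h = config$manual_h, manual_v = config$manual_v)
        write_plot_grid(plots, file.path(config$out_dir, "plot_masks.csv"))
      }
      rec <- measure_static_traits(al$chm, al$ortho_crop, plots, d$das,
                                   traits = config$traits,
                                   scale_height = config$scale_height,
                                   scale_canopy = config$scale_canopy,
                                   scale_seedling = config$scale_seedling)
      write_trait_table(rec, file.path(config$out_dir, sprintf("traits_das%03d.csv", d$das)))
      write_raster(render_height_map(al$chm),
                   file.path(config$out_dir, sprintf("heightmap_das%03d.png", d$das)))
      rec
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (i == ref) stop(res)
      warning(sprintf("date %d (DAS %g) failed: %s; skipped", i, d$das,
                      conditionMessage(res)), call. = FALSE)
      note("failed", i, 0, t0)
      next
    }
    records[[i]] <- res
    note("traits", i, if (is.null(plots)) 0 else nrow(plots), t0)
  }
  trait_table <- do.call(rbind, records[!vapply(records, is.null, TRUE)])
  write_trait_table(trait_table, file.path(config$out_dir, "traits_merged.csv"))
  t0 <- Sys.time()
  dyn_traits <- intersect(config$traits,
                          c("h90", "h95", "h50", "cci", "exg", "exg_norm", "gli",
                            "vari", "ndyi", "nvi"))
  dyn <- dynamic_phenotype_table(trait_table[trait_table$trait %in% dyn_traits, ])
  utils::write.csv(format_dynamic_table(dyn),
                   file.path(config$out_dir, "dynamics.csv"), row.names = FALSE, quote = FALSE)
  note("dynamics", NA, nrow(dyn), t0)
  log_df <- do.call(rbind, log)
  utils::write.csv(log_df, file.path(config$out_dir, "run_log.csv"), row.names = FALSE, quote = FALSE)
  invisible(list(trait_table = trait_table, dynamics = dyn, plots = plots, log = log_df))
}

# logical matrix marking raster cells containing at least one point,
# optionally dilated by `dilate` cells (8-neighbourhood)
cell_occupancy <- function(points, grid, dilate = 0) {
  d <- dim(grid)
  cc <- pmin(pmax(floor((points$x - grid$origin[1]) / grid$res) + 1L, 1L), d[2])
  rr <- pmin(pmax(floor((grid$origin[2] - points$y) / grid$res) + 1L, 1L), d[1])
  occ <- matrix(FALSE, d[1], d[2])
  occ[cbind(rr, cc)] <- TRUE
  while (dilate > 0) {
    p <- matrix(FALSE, d[1] + 2, d[2] + 2)
    p[2:(d[1] + 1), 2:(d[2] + 1)] <- occ
    for (dr in -1:1) for (dc in -1:1) {
      occ <- occ | p[2:(d[1] + 1) + dr, 2:(d[2] + 1) + dc]
    }
    dilate <- dilate - 1
  }
  occ
}

format_dynamic_table <- function(dyn) {
  num <- vapply(dyn, is.numeric, TRUE)
  dyn[num] <- lapply(dyn[num], function(v) ifelse(is.na(v), "NA", sprintf("%.6g", v)))
  dyn
}

#' Render a genotype x date performance matrix
#'
#' A montage image with one column per genotype (in the provided group
#' order) and one row per date, each cell showing that plot's aligned
#' crop; missing cells render as blank placeholders. Cell labels are
#' drawn along the margins.
#'
#' @param crops nested list: `crops[[date]][[genotype]]` is an RGB
#'   [raster_grid] or `NULL`.
#' @param genotypes column order (e.g. grouped by domestication type).
#' @param dates row labels.
#' @param path output PNG path.
#' @param cell_px cell size in px (default 80).
#' @return `path`, invisibly.
#' @export
performance_matrix <- function(crops, genotypes, dates, path, cell_px = 80) {
  n_c <- length(genotypes); n_r <- length(dates)
  stopifnot(n_c >= 1, n_r >= 1)
  mar <- 40 # label margin
  W <- mar + n_c * cell_px; H <- mar + n_r * cell_px
  canvas <- array(1, c(H, W, 3)) # white
  for (ri in seq_len(n_r)) {
    for (ci in seq_len(n_c)) {
      cell <- crops[[ri]][[genotypes[ci]]]
      r0 <- mar + (ri - 1) * cell_px; c0 <- mar + (ci - 1) * cell_px
      block <- array(0.85, c(cell_px, cell_px, 3)) # grey placeholder
      if (!is.null(cell)) {
        h <- structure(diag(3) * c(cell_px / dim(cell)[2], cell_px / dim(cell)[1], 1),
                       class = "homography")
        h[1, 1] <- cell_px / dim(cell)[2]; h[2, 2] <- cell_px / dim(cell)[1]
        w <- warp_raster(cell, h, cell_px, cell_px)
        vals <- w$values / 255
        vals[is.na(vals)] <- 1
        block <- vals
      }
      canvas[(r0 + 1):(r0 + cell_px), (c0 + 1):(c0 + cell_px), ] <- block
      canvas[r0 + 1, (c0 + 1):(c0 + cell_px), ] <- 0 # cell border
      canvas[(r0 + 1):(r0 + cell_px), c0 + 1, ] <- 0
    }
  }
  grDevices::png(path, width = W, height = H)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new(); graphics::plot.window(c(0, W), c(H, 0), xaxs = "i", yaxs = "i")
  graphics::rasterImage(canvas, 0, H, W, 0, interpolate = FALSE)
  for (ci in seq_len(n_c)) {
    graphics::text(mar + (ci - 0.5) * cell_px, mar / 2, genotypes[ci], cex = 0.8)
  }
  for (ri in seq_len(n_r)) {
    graphics::text(mar / 2, mar + (ri - 0.5) * cell_px, dates[ri], cex = 0.8, srt = 90)
  }
  graphics::par(op)
  grDevices::dev.off()
  invisible(path)
}

#' Extract aligned per-plot crops
#'
#' @param raster an aligned [raster_grid].
#' @param grid a `plot_grid` in the same frame.
#' @return named list of [raster_grid] crops keyed by `plot_id`.
#' @export
plot_crops <- function(raster, grid) {
  out <- lapply(seq_len(nrow(grid)), function(i) {
    crop_raster(raster, unlist(grid[i, c("r0", "c0", "r1", "c1")]))
  })
  names(out) <- grid$plot_id
  out
}
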