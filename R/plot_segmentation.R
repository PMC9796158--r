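#' ISODATA (iterative self-organizing) threshold
#'
#' Ridler-Calvard style iteration: starting from the global mean, the
#' threshold is repeatedly replaced by the midpoint of the means of the
#' two classes it induces, until it moves by less than 0.5. The mask
#' marks cells strictly above the converged threshold.
#'
#' @param grey a [raster_grid] or numeric matrix with at least 2 distinct
#'   values.
#' @return list with `threshold` (numeric) and `mask` (logical matrix,
#'   `TRUE` = above threshold).
#' @export
isodata_threshold <- function(grey) {
  v <- if (inherits(grey, "raster_grid")) grey$values else grey
  vals <- v[!is.na(v)]
  if (length(unique(vals)) < 2) stop("ISODATA threshold undefined for a constant image", call. = FALSE)
  t <- mean(vals)
  repeat {
    lo <- vals[vals <= t]; hi <- vals[vals > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < 0.5) { t <- t_new; break }
    t <- t_new
  }
  list(threshold = t, mask = !is.na(v) & v > t)
}

#' Detect grid boundary lines with a restricted Hough transform
#'
#' The evidence is the complement of the vegetation mask: the bare gaps
#' between plots vote for lines. Votes are accumulated in (theta, rho)
#' space with theta restricted to the requested orientation
#' (+/- `angle_tol_deg`); accumulator peaks with at least
#' `vote_frac x (relevant image dimension)` votes are reported by the
#' axis intercept of the line at the image centre. Candidate positions
#' are returned unmerged (see [merge_adjacent_lines()]).
#'
#' @param mask logical matrix, `TRUE` = vegetation (the complement is the
#'   line evidence).
#' @param orientation `"horizontal"` (constant-row lines) or `"vertical"`.
#' @param angle_tol_deg angular search window around the axis (default 5).
#' @param vote_frac fraction of the relevant dimension a peak must reach
#'   (default 0.8: a boundary line runs essentially the full image, while
#'   an oblique chord can stay inside a gap band for at most ~0.7 of it).
#' @return a `line_set`: list with `orientation` and sorted `positions`
#'   (pixel offsets, 0-based boundary coordinates) plus the image extent.
#' @export
detect_grid_lines <- function(mask, orientation = c("horizontal", "vertical"),
                              angle_tol_deg = 5, vote_frac = 0.8) {
  orientation <- match.arg(orientation)
  if (vote_frac <= 0 || vote_frac > 1) stop("vote_frac must be in (0, 1]", call. = FALSE)
  stopifnot(is.logical(mask))
  h <- nrow(mask); w <- ncol(mask)
  ev <- which(!mask, arr.ind = TRUE)
  limit <- if (orientation == "horizontal") h else w
  out <- line_set(orientation, numeric(0), limit)
  if (!nrow(ev)) return(out)
  # pixel centres, x = col - 0.5, y = row - 0.5
  px <- ev[, 2] - 0.5; py <- ev[, 1] - 0.5
  base <- if (orientation == "horizontal") 90 else 0 # normal angle of the line
  thetas <- (base + seq(-angle_tol_deg, angle_tol_deg, by = 1)) * pi / 180
  need <- vote_frac * (if (orientation == "horizontal") w else h)
  cx <- w / 2; cy <- h / 2
  positions <- numeric(0)
  for (th in thetas) {
    rho <- floor(px * cos(th) + py * sin(th) + 0.5) # half-up, not banker's rounding
    tab <- table(rho)
    peaks <- as.numeric(names(tab)[tab >= need])
    if (!length(peaks)) next
    # intercept of the line with the centre axis of the image
    pos <- if (orientation == "horizontal") (peaks - cx * cos(th)) / sin(th)
           else (peaks - cy * sin(th)) / cos(th)
    positions <- c(positions, pos)
  }
  positions <- sort(unique(round(positions)))
  positions <- positions[positions > 0 & positions < limit]
  line_set(orientation, positions, limit)
}

line_set <- function(orientation, positions, limit) {
  positions <- sort(as.numeric(positions))
  if (anyDuplicated(positions)) positions <- unique(positions)
  structure(list(orientation = orientation, positions = positions, limit = limit),
            class = "line_set")
}

#' @export
print.line_set <- function(x, ...) {
  cat(sprintf("<line_set> %s, %d position(s) in (0, %g)\n",
              x$orientation, length(x$positions), x$limit))
  invisible(x)
}

#' Merge adjacent boundary lines
#'
#' Single-linkage clustering of line positions: positions closer than
#' `min_gap_px` join one cluster, and each cluster is replaced by its
#' rounded mean, re-merging until all pairwise gaps are at least
#' `min_gap_px`.
#'
#' @param lines a `line_set`.
#' @param min_gap_px minimum allowed gap between surviving lines (> 0).
#' @return a `line_set` with merged positions.
#' @export
merge_adjacent_lines <- function(lines, min_gap_px) {
  if (min_gap_px <= 0) stop("min_gap_px must be positive", call. = FALSE)
  pos <- lines$positions
  repeat {
    if (length(pos) < 2) break
    gaps <- diff(pos)
    if (all(gaps >= min_gap_px)) break
    cluster <- cumsum(c(1, as.integer(gaps >= min_gap_px)))
    pos <- as.numeric(round(tapply(pos, cluster, mean)))
  }
  line_set(lines$orientation, pos, lines$limit)
}

#' Add manually drawn boundary lines
#'
#' Unions extra positions into the line set, then re-applies the same
#' merge rule so a duplicate of an existing line is absorbed.
#'
#' @param lines a `line_set`.
#' @param extra numeric positions within (0, image extent).
#' @param min_gap_px merge distance (default 1, i.e. only exact overlaps
#'   collapse).
#' @return a `line_set`.
#' @export
add_manual_lines <- function(lines, extra, min_gap_px = 1) {
  extra <- as.numeric(extra)
  if (any(extra <= 0 | extra >= lines$limit)) {
    stop(sprintf("manual line position outside (0, %g)", lines$limit), call. = FALSE)
  }
  merged <- line_set(lines$orientation, c(lines$positions, extra), lines$limit)
  merge_adjacent_lines(merged, min_gap_px)
}

#' Assemble labelled plot masks from boundary lines
#'
#' Image borders count as implicit outer boundaries, so `n` interior
#' horizontal lines delimit `n + 1` plot rows. Cells are half-open pixel
#' boxes between consecutive boundaries, labelled row-major from the
#' top-left according to the trial layout.
#'
#' @param h_lines,v_lines `line_set`s of interior horizontal / vertical
#'   boundaries.
#' @param layout a `trial_layout`.
#' @param dims image size `c(n_rows_px, n_cols_px)`.
#' @return a `plot_grid`: data frame (`row`, `col`, `plot_id`, `r0`, `c0`,
#'   `r1`, `c1`) with attributes `scale` (= 1), `dims`.
#' @export
assemble_plot_grid <- function(h_lines, v_lines, layout, dims) {
  n_rows <- attr(layout, "n_rows"); n_cols <- attr(layout, "n_cols")
  hb <- unique(round(c(0, h_lines$positions, dims[1])))
  vb <- unique(round(c(0, v_lines$positions, dims[2])))
  if (length(hb) - 1 != n_rows || length(vb) - 1 != n_cols) {
    stop(sprintf(paste0("segmentation error: layout expects %d x %d plots ",
                        "but boundaries give %d x %d"),
                 n_rows, n_cols, length(hb) - 1, length(vb) - 1), call. = FALSE)
  }
  cells <- as.data.frame(layout)
  cells$r0 <- hb[cells$row]; cells$r1 <- hb[cells$row + 1]
  cells$c0 <- vb[cells$col]; cells$c1 <- vb[cells$col + 1]
  plot_grid_obj(cells, scale = 1, dims = dims)
}

plot_grid_obj <- function(cells, scale, dims) {
  rownames(cells) <- NULL
  structure(cells[, c("row", "col", "plot_id", "r0", "c0", "r1", "c1")],
            scale = scale, dims = as.integer(dims),
            class = c("plot_grid", "data.frame"))
}

#' Shrink plot masks about their centroids
#'
#' Each rectangle is scaled linearly about its centre (`width' = scale x
#' width`), rounded to whole pixels; labels are preserved. Used to remove
#' plot-edge effects and inter-plot overlap; typical scales are 0.25-0.3
#' for height, 0.7 for canopy/colour and 0.9 for seedling measurements.
#'
#' @param grid a `plot_grid`.
#' @param scale factor in (0, 1].
#' @return a `plot_grid` with shrunken boxes; its `scale` attribute is the
#'   cumulative scale applied since assembly.
#' @export
scale_plot_grid <- function(grid, scale) {
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
  if (scale == 1) return(grid)
  cells <- as.data.frame(grid)
  rc <- (cells$r0 + cells$r1) / 2
  cc <- (cells$c0 + cells$c1) / 2
  hh <- (cells$r1 - cells$r0) * scale / 2
  hw <- (cells$c1 - cells$c0) * scale / 2
  cells$r0 <- round(rc - hh); cells$r1 <- pmax(round(rc + hh), round(rc - hh) + 1)
  cells$c0 <- round(cc - hw); cells$c1 <- pmax(round(cc + hw), round(cc - hw) + 1)
  plot_grid_obj(cells, scale = attr(grid, "scale") * scale, dims = attr(grid, "dims"))
}

#' Segment a field-level CHM into labelled plots
#'
#' End-to-end convenience: ISODATA threshold on the CHM, Hough line
#' detection in both orientations on the gap evidence, merge with a gap
#' distance of half the expected plot pitch (from the layout and image
#' dims), optional manual lines, then assembly against the layout. Fully
#' deterministic.
#'
#' @param chm an aligned CHM [raster_grid] (cm).
#' @param layout a `trial_layout`.
#' @param angle_tol_deg,vote_frac see [detect_grid_lines()].
#' @param manual_h,manual_v optional manual boundary positions (px).
#' @return a `plot_grid`.
#' @export
segment_plots <- function(chm, layout, angle_tol_deg = 5, vote_frac = 0.8,
                          manual_h = NULL, manual_v = NULL) {
  iso <- isodata_threshold(chm)
  dims <- dim(chm)
  n_rows <- attr(layout, "n_rows"); n_cols <- attr(layout, "n_cols")
  hl <- detect_grid_lines(iso$mask, "horizontal", angle_tol_deg, vote_frac)
  vl <- detect_grid_lines(iso$mask, "vertical", angle_tol_deg, vote_frac)
  gap_h <- dims[1] / n_rows / 2
  gap_v <- dims[2] / n_cols / 2
  hl <- merge_adjacent_lines(hl, gap_h)
  vl <- merge_adjacent_lines(vl, gap_v)
  # lines within merge distance of the border are the border itself
  hl <- line_set("horizontal", hl$positions[hl$positions >= gap_h & hl$positions <= dims[1] - gap_h], dims[1])
  vl <- line_set("vertical", vl$positions[vl$positions >= gap_v & vl$positions <= dims[2] - gap_v], dims[2])
  if (!is.null(manual_h)) hl <- add_manual_lines(hl, manual_h, gap_h)
  if (!is.null(manual_v)) vl <- add_manual_lines(vl, manual_v, gap_v)
  assemble_plot_grid(hl, vl, layout, dims)
}

#' Write plot boundaries as CSV
#'
#' @param grid a `plot_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_grid <- function(grid, path) {
  cells <- as.data.frame(grid)
  cells$scale <- attr(grid, "scale")
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
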