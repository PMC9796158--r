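#' Point cloud container
#'
#' A `point_cloud` is a data frame with coordinate columns `x`, `y`, `z`
#' in metres, optional colour columns `r`, `g`, `b` (0-255), and an
#' optional `label` column with values in `ground`, `aboveground`,
#' `outlier`.
#'
#' @param xyz numeric matrix or data frame with 3 columns (x, y, z), metres.
#' @param colours optional matrix/data frame with columns r, g, b in 0-255.
#' @param labels optional character vector, one label per point.
#' @return a `point_cloud` data frame.
#' @export
point_cloud <- function(xyz, colours = NULL, labels = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) < 3) stop("xyz needs 3 columns", call. = FALSE)
  if (!all(is.finite(xyz[, 1:3]))) stop("point coordinates must be finite", call. = FALSE)
  pc <- data.frame(x = as.numeric(xyz[, 1]), y = as.numeric(xyz[, 2]),
                   z = as.numeric(xyz[, 3]))
  if (!is.null(colours)) {
    colours <- as.matrix(colours)
    stopifnot(nrow(colours) == nrow(pc), ncol(colours) == 3)
    pc$r <- as.numeric(colours[, 1]); pc$g <- as.numeric(colours[, 2])
    pc$b <- as.numeric(colours[, 3])
  }
  if (!is.null(labels)) {
    if (length(labels) != nrow(pc)) stop("labels must cover every point", call. = FALSE)
    bad <- setdiff(unique(labels), c("ground", "aboveground", "outlier"))
    if (length(bad)) stop(sprintf("unknown point label(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
    pc$label <- as.character(labels)
  }
  class(pc) <- c("point_cloud", "data.frame")
  pc
}

#' Read a point cloud
#'
#' Two dialects are supported. `xyz-text` (the dialect of record) is one
#' point per line, whitespace-separated `x y z [r g b]`, coordinates in
#' metres. `las` is the binary LAS exchange format (versions 1.0-1.4,
#' point record formats 0-5); coordinates are descaled to metres on read
#' and RGB, when stored, is rescaled to 0-255.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"xyz"` or `"las"`.
#' @return a [point_cloud].
#' @export
read_point_cloud <- function(path, format = c("auto", "xyz", "las")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("point cloud file not found: %s", path), call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.las$", path, ignore.case = TRUE)) "las" else "xyz"
  }
  if (format == "las") return(read_las(path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop(sprintf("empty point cloud file: %s", path), call. = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != nf[1]) || !nf[1] %in% c(3L, 6L)) {
    bad <- which(!nf %in% c(3L, 6L) | nf != nf[1])[1]
    stop(sprintf("parse error in %s at line %d: expected 3 or 6 fields, found %d",
                 path, bad, nf[bad]), call. = FALSE)
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / nf[1])
    stop(sprintf("parse error in %s at line %d: non-numeric token", path, bad), call. = FALSE)
  }
  m <- matrix(vals, ncol = nf[1], byrow = TRUE)
  point_cloud(m[, 1:3, drop = FALSE],
              colours = if (nf[1] == 6L) m[, 4:6, drop = FALSE])
}

#' Write a point cloud as whitespace xyz text
#'
#' @param cloud a [point_cloud].
#' @param path output path.
#' @param digits significant digits for coordinates (default keeps
#'   round-trips within 1e-6 m for field-scale coordinates).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, digits = 9) {
  has_rgb <- all(c("r", "g", "b") %in% names(cloud))
  fmt <- paste0("%.", digits, "g")
  cols <- lapply(c("x", "y", "z"), function(n) sprintf(fmt, cloud[[n]]))
  if (has_rgb) cols <- c(cols, lapply(c("r", "g", "b"), function(n) sprintf("%d", as.integer(round(cloud[[n]])))))
  writeLines(do.call(paste, cols), path)
  invisible(path)
}

# --- LAS binary reader (header + xyz [+ rgb]); no installed R package reads LAS.
read_las <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 227 || rawToChar(raw[1:4]) != "LASF") {
    stop(sprintf("%s is not a LAS file (missing LASF signature)", path), call. = FALSE)
  }
  u8 <- function(off) as.integer(raw[off + 1])
  u16 <- function(off) readBin(raw[off + 1:2], "integer", size = 2, signed = FALSE, endian = "little")
  u32 <- function(off) readBin(raw[off + 1:4], "integer", size = 4, endian = "little")
  dbl <- function(off) readBin(raw[off + 1:8], "double", size = 8, endian = "little")
  ver <- c(u8(24), u8(25))
  if (ver[1] != 1 || ver[2] > 4) {
    stop(sprintf("unsupported LAS version %d.%d in %s", ver[1], ver[2], path), call. = FALSE)
  }
  data_off <- u32(96)
  fmt <- bitwAnd(u8(104), 63L)
  rec_len <- u16(105)
  n_pts <- u32(107)
  if (n_pts == 0 && ver[2] >= 4) {
    n_pts <- readBin(raw[247 + 1:8], "double", size = 8, endian = "little") # uint64; exact below 2^53
  }
  if (!fmt %in% 0:5) stop(sprintf("unsupported LAS point format %d in %s", fmt, path), call. = FALSE)
  scale <- c(dbl(131), dbl(139), dbl(147))
  offset <- c(dbl(155), dbl(163), dbl(171))
  need <- data_off + n_pts * rec_len
  if (length(raw) < need) stop(sprintf("truncated LAS file %s: %d bytes, need %d", path, length(raw), need), call. = FALSE)
  idx <- data_off + rep((seq_len(n_pts) - 1) * rec_len, each = 12) + rep(0:11, n_pts)
  xyz_int <- matrix(readBin(raw[idx + 1], "integer", n = 3 * n_pts, size = 4, endian = "little"),
                    ncol = 3, byrow = TRUE)
  xyz <- sweep(sweep(xyz_int, 2, scale, "*"), 2, offset, "+")
  colours <- NULL
  rgb_off <- c(`2` = 20L, `3` = 28L, `5` = 28L)[as.character(fmt)]
  if (!is.na(rgb_off)) {
    cidx <- data_off + rep((seq_len(n_pts) - 1) * rec_len, each = 6) + rep(rgb_off + 0:5, n_pts)
    rgb16 <- matrix(readBin(raw[cidx + 1], "integer", n = 3 * n_pts, size = 2,
                            signed = FALSE, endian = "little"), ncol = 3, byrow = TRUE)
    colours <- round(rgb16 / 257)
  }
  point_cloud(xyz, colours = colours)
}

# Minimal LAS 1.2 writer (point format 0 or 2); used to build test fixtures
# in code so no binary files ship with the package.
write_las <- function(cloud, path, scale = 0.001) {
  has_rgb <- all(c("r", "g", "b") %in% names(cloud))
  fmt <- if (has_rgb) 2L else 0L
  rec_len <- if (has_rgb) 26L else 20L
  n <- nrow(cloud)
  offset <- c(0, 0, 0)
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("LASF", con, 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2, endian = "little")     # source id, encoding
  writeBin(rep(0L, 4), con, size = 4, endian = "little")     # guid 1-4 (16 bytes)
  writeBin(as.raw(c(1, 2)), con)                             # version 1.2
  writeChar(strrep(" ", 64), con, 64, eos = NULL)            # system id + software
  writeBin(c(0L, 2026L), con, size = 2, endian = "little")   # day, year
  writeBin(227L, con, size = 2, endian = "little")           # header size
  writeBin(227L, con, size = 4, endian = "little")           # data offset
  writeBin(0L, con, size = 4, endian = "little")             # n VLRs
  writeBin(as.raw(fmt), con)
  writeBin(rec_len, con, size = 2, endian = "little")
  writeBin(n, con, size = 4, endian = "little")              # n points
  writeBin(rep(0L, 5), con, size = 4, endian = "little")     # points by return
  writeBin(c(scale, scale, scale, offset), con, size = 8, endian = "little")
  writeBin(as.numeric(c(max(cloud$x), min(cloud$x), max(cloud$y), min(cloud$y),
                        max(cloud$z), min(cloud$z))), con, size = 8, endian = "little")
  xyz_int <- round(sweep(as.matrix(cloud[, c("x", "y", "z")]), 2, offset, "-") / scale)
  for (i in seq_len(n)) {
    writeBin(as.integer(xyz_int[i, ]), con, size = 4, endian = "little")
    writeBin(raw(8), con)                                    # intensity..point source id
    if (has_rgb) {
      writeBin(as.integer(round(c(cloud$r[i], cloud$g[i], cloud$b[i]) * 257)),
               con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read a region-of-interest corner table
#'
#' The ROI dialect is a CSV with columns `name,x,y[,z]` holding at least
#' the four corner markers of the trial region (one planar coordinate
#' frame in metres, y increasing upwards). Corners are re-ordered to the
#' canonical cycle top-left, top-right, bottom-right, bottom-left by
#' their angle around the centroid, so any input ordering of a convex
#' quad yields the same quad.
#'
#' @param path CSV path.
#' @return a `roi_quad`: data frame of 4 corners (`name`, `x`, `y`, and
#'   `z` if present) in canonical order.
#' @export
read_roi <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(tab))) stop("ROI table needs columns name,x,y[,z]", call. = FALSE)
  if (nrow(tab) < 4) stop(sprintf("ROI table has %d rows; at least 4 corners required", nrow(tab)), call. = FALSE)
  roi_quad(tab[seq_len(4), , drop = FALSE])
}

#' Construct a canonical ROI quad from 4 corners
#'
#' @param corners data frame or matrix with `x`, `y` columns, 4 rows.
#' @return a `roi_quad` in canonical corner order.
#' @export
roi_quad <- function(corners) {
  corners <- as.data.frame(corners)
  if (is.null(corners$x)) { names(corners)[1:2] <- c("x", "y") }
  if (nrow(corners) != 4) stop("an ROI quad has exactly 4 corners", call. = FALSE)
  if (anyDuplicated(corners[, c("x", "y")])) stop("ROI corners must be distinct", call. = FALSE)
  cx <- mean(corners$x); cy <- mean(corners$y)
  ang <- atan2(corners$y - cy, corners$x - cx)
  ord <- order(-ang) # clockwise for y-up coordinates
  # rotate the cycle so it starts at the corner nearest the up-left
  # diagonal (angle 135 degrees)
  dist135 <- abs(ang[ord] - 3 * pi / 4)
  dist135 <- pmin(dist135, 2 * pi - dist135)
  start <- which.min(dist135)
  ord <- ord[((seq_len(4) + start - 2) %% 4) + 1]
  q <- corners[ord, , drop = FALSE]
  rownames(q) <- c("top_left", "top_right", "bottom_right", "bottom_left")
  area <- abs(sum(q$x * c(q$y[-1], q$y[1]) - c(q$x[-1], q$x[1]) * q$y)) / 2
  if (area < 1e-12) stop("ROI corners are collinear", call. = FALSE)
  class(q) <- c("roi_quad", "data.frame")
  q
}

#' Read or construct a trial layout
#'
#' A trial layout maps every (row, col) cell of the gridded trial to a
#' plot/genotype identifier. The CSV dialect has columns
#' `row,col,plot_id` (1-based indices) and must cover every cell of the
#' implied `n_rows x n_cols` grid exactly once.
#'
#' @param path CSV path.
#' @return a `trial_layout`: data frame (`row`, `col`, `plot_id`) with
#'   attributes `n_rows`, `n_cols`.
#' @export
read_layout <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("row", "col", "plot_id") %in% names(tab))) {
    stop("layout table needs columns row,col,plot_id", call. = FALSE)
  }
  trial_layout(max(tab$row), max(tab$col), tab)
}

#' @param n_rows,n_cols grid dimensions.
#' @param labels optional data frame (`row`, `col`, `plot_id`); default
#'   labels are `"R<r>C<c>"`, row-major.
#' @rdname read_layout
#' @export
trial_layout <- function(n_rows, n_cols, labels = NULL) {
  if (is.null(labels)) {
    labels <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))[, c("row", "col")]
    labels$plot_id <- sprintf("R%dC%d", labels$row, labels$col)
  }
  labels <- as.data.frame(labels)[, c("row", "col", "plot_id")]
  want <- paste(rep(seq_len(n_rows), each = n_cols), rep(seq_len(n_cols), n_rows))
  have <- paste(labels$row, labels$col)
  if (!setequal(want, have) || anyDuplicated(have)) {
    stop(sprintf("layout labels must cover the %d x %d grid exactly once", n_rows, n_cols), call. = FALSE)
  }
  if (anyDuplicated(labels$plot_id)) stop("plot_id values must be unique", call. = FALSE)
  labels <- labels[order(labels$row, labels$col), ]
  rownames(labels) <- NULL
  structure(labels, n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            class = c("trial_layout", "data.frame"))
}

#' Write plot-trait measurements as CSV
#'
#' One row per (plot, day, trait) measurement, sorted by plot, then days
#' after sowing, then trait name, so identical inputs always produce
#' byte-identical files.
#'
#' @param records data frame with columns `plot_id`, `das`, `trait`, `value`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(records, path) {
  need <- c("plot_id", "das", "trait", "value")
  if (!all(need %in% names(records))) {
    stop("trait records need columns plot_id, das, trait, value", call. = FALSE)
  }
  records <- as.data.frame(records)[, need]
  key <- paste(records$plot_id, records$das, records$trait, sep = "\r")
  if (anyDuplicated(key)) {
    stop(sprintf("duplicate (plot, das, trait) record: %s",
                 gsub("\r", "/", key[duplicated(key)][1])), call. = FALSE)
  }
  records <- records[order(records$plot_id, records$das, records$trait), ]
  utils::write.csv(format_trait_values(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_trait_values <- function(records) {
  records$value <- ifelse(is.na(records$value), "NA", sprintf("%.6g", records$value))
  records
}

#' Read a plot-trait table written by [write_trait_table()]
#'
#' @param path CSV path.
#' @return data frame with columns `plot_id`, `das`, `trait`, `value`.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_id", "das", "trait", "value")
  if (!all(need %in% names(tab))) stop("trait table needs columns plot_id, das, trait, value", call. = FALSE)
  tab[, need]
}
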