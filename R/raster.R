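#' Raster grid container
#'
#' A `raster_grid` is a row-major 2D value grid with the origin at the
#' top-left pixel and 0-based half-open pixel boxes `[r0, r1) x [c0, c1)`.
#' Greyscale grids are numeric matrices (row 1 is the top image row); RGB
#' grids are `nrow x ncol x 3` arrays. `NA` cells are no-data. World
#' coordinates, when meaningful, are carried by `origin` (x, y of the
#' top-left corner in metres) and `res` (metres per pixel).
#'
#' @param values numeric matrix (grey) or 3D array with third dim 3 (RGB).
#' @param res metres per pixel (isotropic).
#' @param origin world (x, y) of the top-left grid corner.
#' @param bitdepth integer sample depth used when the grid is written to
#'   disk: 8 or 16 for greyscale, 8 for RGB. `NULL` means floating point
#'   (never written as an image without explicit scaling).
#' @return a `raster_grid` object.
#' @export
raster_grid <- function(values, res = 1, origin = c(0, 0), bitdepth = NULL) {
  if (is.matrix(values)) {
    channels <- 1L
  } else if (is.array(values) && length(dim(values)) == 3 && dim(values)[3] == 3) {
    channels <- 3L
  } else {
    stop("`values` must be a matrix or an nrow x ncol x 3 array", call. = FALSE)
  }
  if (!is.null(bitdepth) && !bitdepth %in% c(8L, 16L)) {
    stop("bitdepth must be 8 or 16", call. = FALSE)
  }
  structure(
    list(values = values, res = res, origin = as.numeric(origin[1:2]),
         bitdepth = if (is.null(bitdepth)) NULL else as.integer(bitdepth),
         channels = channels),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)[1:2]

#' @export
print.raster_grid <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<raster_grid> %d x %d px, %s, res %g m/px, origin (%g, %g)\n",
              d[1], d[2], if (x$channels == 3) "RGB" else "grey",
              x$res, x$origin[1], x$origin[2]))
  invisible(x)
}

is_rgb <- function(grid) inherits(grid, "raster_grid") && grid$channels == 3L

rasters_aligned <- function(a, b) {
  identical(dim(a), dim(b)) &&
    isTRUE(all.equal(a$res, b$res)) &&
    isTRUE(all.equal(a$origin, b$origin))
}

#' Extract a sub-grid by a half-open pixel box
#'
#' @param grid a `raster_grid`.
#' @param box integer vector `c(r0, c0, r1, c1)`, 0-based half-open.
#' @return a `raster_grid` covering the box.
#' @export
crop_raster <- function(grid, box) {
  box <- validate_pixel_box(box, dim(grid))
  rows <- (box[1] + 1):box[3]
  cols <- (box[2] + 1):box[4]
  vals <- if (is_rgb(grid)) grid$values[rows, cols, , drop = FALSE]
          else grid$values[rows, cols, drop = FALSE]
  raster_grid(vals, res = grid$res,
              origin = grid$origin + c(box[2], box[1]) * grid$res,
              bitdepth = grid$bitdepth)
}

validate_pixel_box <- function(box, dims) {
  box <- as.numeric(box)
  if (length(box) != 4 || anyNA(box)) stop("pixel box must be c(r0, c0, r1, c1)", call. = FALSE)
  if (box[1] >= box[3] || box[2] >= box[4]) stop("empty pixel box", call. = FALSE)
  if (box[1] < 0 || box[2] < 0 || box[3] > dims[1] || box[4] > dims[2]) {
    stop(sprintf("pixel box [%g,%g)x[%g,%g) outside %d x %d grid",
                 box[1], box[3], box[2], box[4], dims[1], dims[2]), call. = FALSE)
  }
  box
}

#' Read a raster image (PNG)
#'
#' Reads an 8- or 16-bit greyscale or 8-bit RGB PNG into a [raster_grid].
#' Sample values are returned on their native integer scale (0..255 or
#' 0..65535). PNG is the raster dialect of record here; it is lossless for
#' integer grids, so write/read round-trips are bit-exact.
#'
#' @param path file path.
#' @return a `raster_grid`.
#' @export
read_raster <- function(path) {
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path), call. = FALSE)
  arr <- tryCatch(png::readPNG(path, info = TRUE), error = function(e) {
    stop(sprintf("cannot read raster %s: %s", path, conditionMessage(e)), call. = FALSE)
  })
  info <- attr(arr, "info")
  attr(arr, "info") <- NULL
  depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
  scale <- 2^depth - 1
  if (length(dim(arr)) == 2) {
    raster_grid(round(arr * scale), bitdepth = depth)
  } else if (dim(arr)[3] >= 3) {
    if (depth != 8) stop("RGB rasters must be 8-bit", call. = FALSE)
    raster_grid(round(arr[, , 1:3, drop = FALSE] * 255), bitdepth = 8L)
  } else if (dim(arr)[3] == 2) { # grey + alpha
    raster_grid(round(arr[, , 1] * scale), bitdepth = depth)
  } else {
    stop("unsupported channel layout", call. = FALSE)
  }
}

#' Write a raster image (PNG)
#'
#' Integer-valued grids round-trip bit-exactly. A greyscale grid with
#' `bitdepth = NULL` must be rescaled by the caller first.
#'
#' @param grid a `raster_grid` with integer values in the bitdepth range.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_raster <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  depth <- grid$bitdepth
  if (is.null(depth)) stop("grid has no bitdepth; rescale to 8- or 16-bit before writing", call. = FALSE)
  vals <- grid$values
  if (anyNA(vals)) vals[is.na(vals)] <- 0
  scale <- 2^depth - 1
  if (any(vals < 0 | vals > scale)) stop("values outside bitdepth range", call. = FALSE)
  if (depth == 16L) {
    if (is_rgb(grid)) stop("16-bit rasters must be greyscale", call. = FALSE)
    write_png16_grey(vals, path)
  } else {
    png::writePNG(vals / scale, target = path, dpi = NULL)
  }
  invisible(path)
}
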