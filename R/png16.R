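# Minimal 16-bit greyscale PNG encoder. The png package reads 16-bit files
# but only writes 8-bit, so height grids that need a 16-bit store are
# encoded here: IHDR (grey, depth 16), one zlib IDAT (filter 0 per row),
# IEND. memCompress(type = "gzip") emits a zlib stream, which is the IDAT
# payload format.

crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) == 1L) bitwXor(-306674912L, bitwShiftR(bitwAnd(c, -2L), 1)) # 0xEDB88320
           else bitwShiftR(bitwAnd(c, -2L), 1)
      c <- bitwAnd(c, -1L)
    }
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L # 0xFFFFFFFF
  for (b in as.integer(bytes)) {
    idx <- bitwAnd(bitwXor(crc, b), 255L)
    crc <- bitwXor(bitwShiftR(bitwAnd(crc, -256L), 8), crc32_table[idx + 1])
  }
  bitwXor(crc, -1L)
}

int_to_be4 <- function(x) {
  x <- as.numeric(x) %% 2^32
  as.raw(c(x %/% 2^24, (x %/% 2^16) %% 256, (x %/% 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  crc <- crc32(body)
  c(int_to_be4(length(data)), body, int_to_be4(if (crc < 0) crc + 2^32 else crc))
}

write_png16_grey <- function(counts, path) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0 | counts > 65535)) stop("values outside 16-bit range", call. = FALSE)
  h <- nrow(counts); w <- ncol(counts)
  m <- round(t(counts)) # column of t() = image row
  hi <- as.raw(m %/% 256); lo <- as.raw(m %% 256)
  scan <- raw((2 * w + 1) * h)
  for (r in seq_len(h)) {
    off <- (r - 1) * (2 * w + 1)
    scan[off + 1] <- as.raw(0) # filter type 0
    idx <- ((r - 1) * w + 1):(r * w)
    scan[off + 1 + 2 * seq_len(w) - 1] <- hi[idx]
    scan[off + 1 + 2 * seq_len(w)] <- lo[idx]
  }
  ihdr <- c(int_to_be4(w), int_to_be4(h),
            as.raw(c(16, 0, 0, 0, 0))) # depth 16, grey, deflate, adaptive, no interlace
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", memCompress(scan, "gzip")), con)
  writeBin(png_chunk("IEND", raw(0)), con)
  invisible(path)
}
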