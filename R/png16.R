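# Minimal 16-bit grayscale PNG encoder.
#
# The png package decodes 16-bit grayscale PNGs but only encodes 8-bit,
# so the 16-bit write path is produced here directly: IHDR/IDAT/IEND
# chunks, scanlines with filter type 0, zlib stream via memCompress()
# (which emits RFC 1950 zlib framing). Output is verified against
# png::readPNG in the test suite.

crc32_table <- local({
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), poly)
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L  # 0xFFFFFFFF
  b <- as.integer(bytes)
  for (i in seq_along(b)) {
    crc <- bitwXor(crc32_table[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L],
                   bitwShiftR(crc, 8L))
  }
  bitwXor(crc, -1L)
}

# Unsigned big-endian 4-byte encoding of a (possibly negative-wrapped)
# 32-bit value.
uint32_be <- function(v) {
  v <- as.numeric(v)
  if (v < 0) v <- v + 2^32
  as.raw(c(v %/% 2^24, (v %/% 2^16) %% 256, (v %/% 2^8) %% 256, v %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(uint32_be(length(data)), body, uint32_be(crc32(body)))
}

# grid: (height x width) matrix of values in [0, 1].
write_png_gray16 <- function(grid, path) {
  h <- nrow(grid); w <- ncol(grid)
  vals <- round(t(grid) * 65535)  # row-major scan order
  hi <- as.raw(vals %/% 256L)
  lo <- as.raw(vals %% 256L)
  samples <- as.raw(rbind(hi, lo))  # big-endian sample pairs
  dim(samples) <- c(2L * w, h)
  scanlines <- rbind(as.raw(0L), samples)  # filter byte 0 per row
  idat <- memCompress(as.raw(scanlines), type = "gzip")
  ihdr <- c(uint32_be(w), uint32_be(h),
            as.raw(c(16L, 0L, 0L, 0L, 0L)))  # depth 16, gray, deflate
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(137L, 80L, 78L, 71L, 13L, 10L, 26L, 10L)), con)
  writeBin(png_chunk("IHDR", ihdr), con)
  writeBin(png_chunk("IDAT", idat), con)
  writeBin(png_chunk("IEND", raw(0L)), con)
  invisible(path)
}
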