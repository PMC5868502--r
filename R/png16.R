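# Minimal 16-bit grayscale PNG encoder.
#
# Base R's memCompress(type = "gzip") emits a zlib (RFC 1950) stream, which
# is exactly the compression format PNG's IDAT chunk requires; only the
# per-chunk CRC-32 has to be supplied here. Reading is delegated to
# png::readPNG, which supports 16-bit natively. No installed R package can
# *write* 16-bit PNG, hence this encoder.

.crc_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (!is.null(.crc_env$table)) return(.crc_env$table)
  poly <- -306674912L # 0xEDB88320 as signed 32-bit
  tab <- integer(256)
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
  .crc_env$table <- tab
  tab
}

crc32 <- function(bytes) {
  tab <- crc32_table()
  b <- as.integer(bytes)
  crc <- -1L # 0xFFFFFFFF
  for (i in seq_along(b)) {
    crc <- bitwXor(bitwShiftR(crc, 8L),
                   tab[bitwAnd(bitwXor(crc, b[i]), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

png_chunk <- function(type, data) {
  type_raw <- charToRaw(type)
  payload <- c(type_raw, data)
  c(writeBin(length(data), raw(), size = 4L, endian = "big"),
    payload,
    writeBin(crc32(payload), raw(), size = 4L, endian = "big"))
}

# counts: numeric/integer matrix in [0, 65535]; written big-endian, one
# filter byte (0 = None) per scanline.
write_png_gray16 <- function(counts, path) {
  stopifnot(is.matrix(counts))
  h <- nrow(counts)
  w <- ncol(counts)
  vals <- as.integer(round(t(counts))) # row-major scan order
  if (any(vals < 0L) || any(vals > 65535L)) {
    stop("pixel values outside 16-bit range")
  }
  hi <- as.raw(vals %/% 256L)
  lo <- as.raw(vals %% 256L)
  samples <- as.raw(rbind(hi, lo)) # interleave to big-endian pairs
  dim(samples) <- NULL
  rows <- matrix(samples, nrow = 2L * w, ncol = h)
  scanlines <- rbind(matrix(as.raw(0L), 1L, h), rows)
  idat <- memCompress(as.raw(scanlines), type = "gzip") # zlib stream
  ihdr <- c(writeBin(w, raw(), size = 4L, endian = "big"),
            writeBin(h, raw(), size = 4L, endian = "big"),
            as.raw(c(16L, 0L, 0L, 0L, 0L))) # depth 16, gray, default coding
  sig <- as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(sig,
             png_chunk("IHDR", ihdr),
             png_chunk("IDAT", idat),
             png_chunk("IEND", raw(0))), con)
  invisible(path)
}

# Read a 16-bit grayscale PNG back into an integer count matrix.
read_png_gray16 <- function(path) {
  img <- png::readPNG(path, info = TRUE)
  info <- attr(img, "info")
  if (!is.null(info$bit.depth) && info$bit.depth != 16L) {
    stop("'", path, "' is not a 16-bit image (bit depth ",
         info$bit.depth, ")")
  }
  if (length(dim(img)) != 2L) {
    stop("'", path, "' is not a single-channel grayscale image")
  }
  matrix(round(img * 65535), nrow(img), ncol(img))
}
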