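# Raster I/O and the image data model.
#
# Images are plain integer matrices wrapped in a light "cfa_image" S3 class;
# pixel values live on the 16-bit scale [0, 65535] regardless of the on-disk
# bit depth, with the source depth recorded. Coordinates are 1-based (row,
# col) and bounding boxes are inclusive [row_min, row_max] x [col_min,
# col_max], the host language's native convention.

#' Construct a CFA image
#'
#' @param pixels Integer (or numeric) matrix of pixel values in
#'   `[0, 65535]`.
#' @param bit_depth Bit depth of the source data (8 or 16). Values are always
#'   stored on the 16-bit scale.
#' @param origin Free-text provenance tag (file path or `"synthetic"`).
#' @return An object of class `"cfa_image"`.
#' @export
cfa_image <- function(pixels, bit_depth = 16L, origin = "synthetic") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) stop("image must be non-empty")
  px <- pixels
  storage.mode(px) <- "integer"
  if (anyNA(px)) stop("pixel values must be finite")
  if (min(px) < 0L || max(px) > 65535L)
    stop("pixel values must lie in [0, 65535]")
  structure(
    list(pixels = px, bit_depth = as.integer(bit_depth), origin = origin),
    class = "cfa_image"
  )
}

#' @export
print.cfa_image <- function(x, ...) {
  cat(sprintf("<cfa_image> %d x %d, %d-bit, range [%d, %d], origin: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$bit_depth,
              min(x$pixels), max(x$pixels), x$origin))
  invisible(x)
}

#' @export
dim.cfa_image <- function(x) dim(x$pixels)

# -- PGM ---------------------------------------------------------------------

# token scanner for PGM headers: whitespace-separated tokens, '#' comments to
# end of line; returns tokens plus the byte offset just past the last token
pgm_header_tokens <- function(raw_bytes, n_tokens) {
  tokens <- character(0)
  i <- 1L
  n <- length(raw_bytes)
  cur <- character(0)
  while (i <= n && length(tokens) < n_tokens) {
    b <- raw_bytes[i]
    ch <- rawToChar(b)
    if (ch == "#") {
      while (i <= n && !(rawToChar(raw_bytes[i]) %in% c("\n", "\r"))) i <- i + 1L
    } else if (grepl("[ \t\r\n]", ch)) {
      if (length(cur)) {
        tokens <- c(tokens, paste0(cur, collapse = ""))
        cur <- character(0)
      }
      i <- i + 1L
    } else {
      cur <- c(cur, ch)
      i <- i + 1L
    }
  }
  if (length(cur) && length(tokens) < n_tokens)
    tokens <- c(tokens, paste0(cur, collapse = ""))
  if (length(tokens) < n_tokens)
    stop(sprintf("malformed PGM header: expected %d tokens, got %d (offset %d)",
                 n_tokens, length(tokens), i))
  list(tokens = tokens, offset = i)
}

#' Read a PGM (Portable Graymap) file
#'
#' Supports the ASCII (`P2`) and binary (`P5`) dialects. Files with
#' `maxval <= 255` are upcast losslessly to the 16-bit scale by multiplying by
#' 257 (so 255 maps to 65535), with the original bit depth recorded; 16-bit
#' binary samples are decoded big-endian per the PGM standard.
#'
#' @param path Path to a PGM file.
#' @return A [cfa_image()] whose `origin` is `path`.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw_bytes <- readBin(path, "raw", n = file.size(path))
  if (length(raw_bytes) < 2L)
    stop("malformed PGM: file too short (offset 0)")
  magic <- rawToChar(raw_bytes[1:2])
  if (!magic %in% c("P2", "P5"))
    stop(sprintf("malformed PGM magic '%s' (offset 0): expected P2 or P5", magic))
  hdr <- pgm_header_tokens(raw_bytes[-(1:2)], 3L)
  dims <- suppressWarnings(as.integer(hdr$tokens))
  if (anyNA(dims) || any(dims <= 0L))
    stop("malformed PGM header: non-numeric or non-positive dimensions/maxval")
  w <- dims[1L]; h <- dims[2L]; maxval <- dims[3L]
  if (maxval > 65535L) stop("unsupported PGM maxval > 65535")
  npix <- w * h
  # hdr$offset indexes the sub-array after the 2-byte magic and already sits
  # past the single whitespace that terminates the header
  body_at <- hdr$offset + 2L
  if (magic == "P2") {
    txt <- rawToChar(raw_bytes[body_at:length(raw_bytes)])
    vals <- suppressWarnings(as.integer(strsplit(trimws(txt), "[ \t\r\n]+")[[1L]]))
    if (length(vals) < npix || anyNA(vals[seq_len(npix)]))
      stop("malformed P2 payload: expected ", npix, " samples")
    vals <- vals[seq_len(npix)]
  } else {
    payload <- raw_bytes[body_at:length(raw_bytes)]
    if (maxval > 255L) {
      if (length(payload) < 2L * npix)
        stop("malformed P5 payload: expected ", 2L * npix, " bytes")
      hi <- as.integer(payload[seq(1L, 2L * npix, by = 2L)])
      lo <- as.integer(payload[seq(2L, 2L * npix, by = 2L)])
      vals <- hi * 256L + lo  # big-endian
    } else {
      if (length(payload) < npix)
        stop("malformed P5 payload: expected ", npix, " bytes")
      vals <- as.integer(payload[seq_len(npix)])
    }
  }
  if (max(vals) > maxval)
    stop("malformed PGM: sample exceeds maxval")
  bit_depth <- if (maxval > 255L) 16L else 8L
  if (maxval <= 255L) vals <- vals * 257L  # lossless 8->16 upcast
  px <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  cfa_image(px, bit_depth = bit_depth, origin = path)
}

#' Write a PGM (Portable Graymap) file
#'
#' Writes a standard-conforming `P5` (binary, default) or `P2` (ASCII) file
#' with `maxval 65535`; 16-bit binary samples are written big-endian. A
#' comment line records the image's provenance tag.
#'
#' @param image A [cfa_image()].
#' @param path Output path.
#' @param ascii If `TRUE` write the ASCII `P2` dialect.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, ascii = FALSE) {
  stopifnot(inherits(image, "cfa_image"))
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  comment <- paste0("# seedcfa origin: ", gsub("[\r\n]", " ", image$origin))
  header <- sprintf("%s\n%s\n%d %d\n65535\n",
                    if (ascii) "P2" else "P5", comment, w, h)
  vals <- as.integer(t(px))  # row-major raster order
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw(header), con)
  if (ascii) {
    writeBin(charToRaw(paste(vals, collapse = "\n")), con)
    writeBin(charToRaw("\n"), con)
  } else {
    bytes <- as.raw(rbind(vals %/% 256L, vals %% 256L))  # big-endian pairs
    writeBin(bytes, con)
  }
  invisible(path)
}

# -- 16-bit grayscale PNG ----------------------------------------------------

# 32-bit XOR on doubles (bitwXor is limited to signed 32-bit integers)
xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

# CRC32 (PNG/IEEE polynomial), table-driven
crc32_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      t <- numeric(256)
      for (n in 0:255) {
        c <- n
        for (k in 1:8) {
          c <- if (c %% 2 == 1) xor32(3988292384, floor(c / 2)) else floor(c / 2)
        }
        t[n + 1] <- c
      }
      tab <<- t
    }
    tab
  }
})

crc32 <- function(bytes) {
  tab <- crc32_table()
  c <- 4294967295
  for (b in as.integer(bytes)) {
    idx <- bitwXor(c %% 256, b) + 1
    c <- xor32(tab[idx], floor(c / 256))
  }
  xor32(c, 4294967295)
}

u32_be <- function(x) {
  as.raw(c(floor(x / 16777216) %% 256, floor(x / 65536) %% 256,
           floor(x / 256) %% 256, x %% 256))
}

png_chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(u32_be(length(data)), body, u32_be(crc32(body)))
}

# zlib (RFC 1950) stream of the filtered scanlines; memCompress's "gzip"
# type emits a zlib stream (0x78 0x9c header + deflate + Adler-32)
zlib_stream <- function(bytes) {
  z <- memCompress(bytes, type = "gzip")
  if (as.integer(z[1L]) != 120L) stop("unexpected compression header")
  z
}

#' Write a 16-bit grayscale PNG
#'
#' Minimal PNG encoder for single-channel 16-bit data (bit depth 16, color
#' type 0, filter 0 scanlines, one zlib-compressed IDAT chunk). Written
#' in-package because the installed raster libraries only write 8-bit PNGs;
#' read-back with [read_crop_png()] (backed by \pkg{png}) is exact.
#'
#' @param pixels Integer matrix of values in `[0, 65535]` (a seed crop).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_crop_png <- function(pixels, path) {
  if (inherits(pixels, "cfa_image")) pixels <- pixels$pixels
  if (!is.matrix(pixels) || nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("empty crop")
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > 65535L)
    stop("pixel values must lie in [0, 65535]")
  h <- nrow(pixels); w <- ncol(pixels)
  vals <- as.integer(t(pixels))
  sample_bytes <- as.raw(rbind(vals %/% 256L, vals %% 256L))  # big-endian
  # prepend filter byte 0 to each scanline
  scan <- matrix(sample_bytes, nrow = 2L * w)
  idat_raw <- as.raw(rbind(as.raw(0L), scan))
  zlib <- zlib_stream(idat_raw)
  ihdr <- c(u32_be(w), u32_be(h), as.raw(c(16L, 0L, 0L, 0L, 0L)))
  out <- c(as.raw(c(0x89, 0x50, 0x4e, 0x47, 0x0d, 0x0a, 0x1a, 0x0a)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", zlib),
           png_chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a grayscale PNG crop back to the 16-bit integer scale
#'
#' @param path Path to a grayscale PNG (8- or 16-bit).
#' @return Integer matrix of pixel values in `[0, 65535]`.
#' @export
read_crop_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 3L) v <- v[, , 1L]
  px <- matrix(as.integer(round(v * 65535)), nrow = nrow(v))
  px
}
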