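# Minimal baseline TIFF support (uncompressed, grayscale, little-endian
# write; little/big-endian read). No TIFF binding is pre-installed in the
# target environment, and the pipeline only needs single-sample rasters, so a
# small strip-based implementation is carried here and cross-checked against
# an external reader in the test suite.

.tiff_types <- c(BYTE = 1L, ASCII = 2L, SHORT = 3L, LONG = 4L, RATIONAL = 5L,
                 SBYTE = 6L, UNDEF = 7L, SSHORT = 8L, SLONG = 9L,
                 SRATIONAL = 10L, FLOAT = 11L, DOUBLE = 12L)
.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Write a grayscale TIFF
#'
#' Writes one or more 2D rasters as an uncompressed, single-strip,
#' little-endian baseline TIFF. Matrices are written row-major (row 1 = top
#' image row). Supported sample formats: `"float"` (32-bit IEEE), `"uint8"`,
#' `"uint16"`.
#'
#' @param x a numeric matrix or a list of matrices (multi-page).
#' @param path output path.
#' @param sample_format one of `"float"`, `"uint8"`, `"uint16"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(x, path, sample_format = c("float", "uint8", "uint16")) {
  sample_format <- match.arg(sample_format)
  pages <- if (is.matrix(x)) list(x) else x
  stopifnot(length(pages) >= 1, all(vapply(pages, is.matrix, logical(1))))
  bits <- switch(sample_format, float = 32L, uint8 = 8L, uint16 = 16L)
  fmt_code <- switch(sample_format, float = 3L, uint8 = 1L, uint16 = 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  # header
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  offset <- 8L
  n_entries <- 9L
  for (p in seq_along(pages)) {
    img <- pages[[p]]
    h <- nrow(img); w <- ncol(img)
    nbytes <- h * w * (bits %/% 8L)
    ifd_size <- 2L + n_entries * 12L + 4L
    data_off <- offset + ifd_size
    entry <- function(tag, type, count, value) {
      w2(tag); w2(.tiff_types[[type]]); w4(count)
      if (type == "SHORT" && count == 1L) { w2(value); w2(0L) } else w4(value)
    }
    w2(n_entries)
    entry(256L, "LONG", 1L, w)           # ImageWidth
    entry(257L, "LONG", 1L, h)           # ImageLength
    entry(258L, "SHORT", 1L, bits)       # BitsPerSample
    entry(259L, "SHORT", 1L, 1L)         # Compression = none
    entry(262L, "SHORT", 1L, 1L)         # Photometric = BlackIsZero
    entry(273L, "LONG", 1L, data_off)    # StripOffsets
    entry(277L, "SHORT", 1L, 1L)         # SamplesPerPixel
    entry(279L, "LONG", 1L, nbytes)      # StripByteCounts
    entry(339L, "SHORT", 1L, fmt_code)   # SampleFormat
    next_ifd <- if (p < length(pages)) data_off + nbytes else 0L
    w4(next_ifd)
    vals <- as.vector(t(img))            # row-major
    if (sample_format == "float") {
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    } else {
      maxv <- if (bits == 8L) 255 else 65535
      iv <- as.integer(round(vals))
      if (any(iv < 0 | iv > maxv)) stop("integer sample out of range for ", sample_format)
      writeBin(iv, con, size = bits %/% 8L, endian = "little")
    }
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Read a grayscale TIFF
#'
#' Reads uncompressed single-sample baseline TIFFs (8/16-bit unsigned or
#' 32-bit float; single or multiple strips; either byte order).
#'
#' @param path TIFF file path.
#' @param pages page indices to read (default all).
#' @return a matrix (single page) or list of matrices.
#' @export
read_tiff <- function(path, pages = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  endian <- if (rawToChar(raw[1:2]) == "II") "little" else "big"
  rd <- function(off, size, n = 1L, what = "integer",
                 signed = (size > 2L)) {
    readBin(raw[(off + 1):(off + size * n)], what, n = n, size = size,
            endian = endian, signed = signed)
  }
  if (rd(2, 2) != 42L) stop("not a TIFF file")
  ifd_off <- rd(4, 4)
  out <- list()
  page <- 0L
  while (ifd_off != 0L) {
    page <- page + 1L
    n_ent <- rd(ifd_off, 2)
    tags <- list()
    for (e in seq_len(n_ent)) {
      base <- ifd_off + 2L + (e - 1L) * 12L
      tag <- rd(base, 2)
      type <- rd(base + 2L, 2)
      count <- rd(base + 4L, 4)
      tsz <- .tiff_type_size[type]
      voff <- if (tsz * count <= 4L) base + 8L else rd(base + 8L, 4)
      vals <- switch(as.character(type),
        `3` = rd(voff, 2, count),
        `4` = rd(voff, 4, count),
        `1` = as.integer(rd(voff, 1, count, signed = FALSE)),
        rd(voff, 4, count))
      tags[[as.character(tag)]] <- vals
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    if (is.null(pages) || page %in% pages) {
      w <- g(256L); h <- g(257L)
      bits <- g(258L, 1L)[1]
      if (g(259L, 1L) != 1L) stop("compressed TIFF not supported")
      if (g(277L, 1L) != 1L) stop("multi-sample TIFF not supported")
      fmt <- g(339L, 1L)[1]
      offs <- g(273L); counts <- g(279L, h * w * bits %/% 8L)
      bytes <- raw(0)
      for (s in seq_along(offs)) {
        bytes <- c(bytes, raw[(offs[s] + 1):(offs[s] + counts[s])])
      }
      n <- h * w
      vals <- if (fmt == 3L && bits == 32L) {
        readBin(bytes, "numeric", n = n, size = 4L, endian = endian)
      } else if (bits == 8L) {
        as.numeric(readBin(bytes, "integer", n = n, size = 1L,
                           endian = endian, signed = FALSE))
      } else if (bits == 16L) {
        as.numeric(readBin(bytes, "integer", n = n, size = 2L,
                           endian = endian, signed = FALSE))
      } else stop("unsupported sample layout (bits=", bits, ", format=", fmt, ")")
      out[[length(out) + 1L]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    }
    ifd_off <- rd(ifd_off + 2L + n_ent * 12L, 4)
    if (!is.null(pages) && page >= max(pages)) break
  }
  if (length(out) == 1L) out[[1]] else out
}
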