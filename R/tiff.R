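# Minimal baseline TIFF I/O for multi-page grayscale stacks.
#
# The package stores simulated stacks as 32-bit float TIFF (one page per
# z-slice) and label masks as 8-bit TIFF, per its external interfaces. No TIFF
# library is assumed: this is a self-contained baseline codec supporting
# exactly what the package writes — little-endian, uncompressed, single
# sample per pixel, one strip per page, unsigned 8/16-bit integer or 32-bit
# IEEE float samples. The reader also accepts multi-strip files produced by
# common writers as long as they are uncompressed grayscale.

TIFF_TYPE_SIZES <- c(1, 1, 2, 4, 8, 1, 1, 2, 4, 8, 4, 8) # BYTE..DOUBLE

#' Write a grayscale multi-page TIFF stack
#'
#' @param pages a numeric matrix, a list of matrices, or a 3D array indexed
#'   `[y, x, page]`. All pages must share one shape.
#' @param path output file path.
#' @param sample_format `"float"` (32-bit IEEE, the default, used for
#'   phase/RI images) or `"uint8"` (used for label masks; values must be
#'   integers in 0..255).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(path, pages, sample_format = c("float", "uint8")) {
  sample_format <- match.arg(sample_format)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L) {
    pages <- lapply(seq_len(dim(pages)[3]), function(k) pages[, , k])
  }
  if (!is.list(pages) || length(pages) == 0L) {
    stop("`pages` must be a matrix, list of matrices, or 3D array")
  }
  dims <- unique(lapply(pages, dim))
  if (length(dims) != 1L) stop("all pages must have identical dimensions")
  nr <- dims[[1]][1]; nc <- dims[[1]][2]
  if (sample_format == "uint8") {
    rng <- range(vapply(pages, function(p) range(p), numeric(2)))
    if (rng[1] < 0 || rng[2] > 255) stop("uint8 pages must lie in [0, 255]")
  }
  bits <- if (sample_format == "float") 32L else 8L
  fmt_code <- if (sample_format == "float") 3L else 1L
  bytes_per_px <- bits / 8L
  strip_bytes <- nr * nc * bytes_per_px
  ifd_size <- 2L + 10L * 12L + 4L

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  # first IFD sits right after the first page's pixel data
  first_ifd <- 8L + strip_bytes
  writeBin(as.integer(first_ifd), con, size = 4, endian = "little")

  write_tag <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3L) { # SHORT inline, left-justified
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }

  n_pages <- length(pages)
  offset <- 8L
  for (k in seq_len(n_pages)) {
    strip_offset <- offset
    v <- as.vector(t(pages[[k]])) # TIFF strips are row-major
    if (sample_format == "float") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      writeBin(as.raw(as.integer(round(v))), con)
    }
    ifd_offset <- strip_offset + strip_bytes
    next_ifd <- if (k < n_pages) ifd_offset + ifd_size + strip_bytes else 0L
    writeBin(10L, con, size = 2, endian = "little")
    write_tag(256L, 4L, 1L, nc)            # ImageWidth
    write_tag(257L, 4L, 1L, nr)            # ImageLength
    write_tag(258L, 3L, 1L, bits)          # BitsPerSample
    write_tag(259L, 3L, 1L, 1L)            # Compression: none
    write_tag(262L, 3L, 1L, 1L)            # Photometric: BlackIsZero
    write_tag(273L, 4L, 1L, strip_offset)  # StripOffsets
    write_tag(277L, 3L, 1L, 1L)            # SamplesPerPixel
    write_tag(278L, 4L, 1L, nr)            # RowsPerStrip
    write_tag(279L, 4L, 1L, strip_bytes)   # StripByteCounts
    write_tag(339L, 3L, 1L, fmt_code)      # SampleFormat
    writeBin(as.integer(next_ifd), con, size = 4, endian = "little")
    offset <- ifd_offset + ifd_size
  }
  invisible(path)
}

#' Read a grayscale multi-page TIFF stack
#'
#' Supports uncompressed little-endian grayscale TIFF with 8/16-bit unsigned
#' or 32-bit float samples (the subset [write_tiff()] produces, plus
#' multi-strip layouts from common writers).
#'
#' @param path file path.
#' @return a list of numeric matrices, one per page, each indexed `[y, x]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  if (rawToChar(raw[1:2]) != "II") {
    stop("only little-endian ('II') TIFF is supported: ", path)
  }
  u16 <- function(off) {
    sum(as.integer(raw[off + 1:2]) * c(1, 256))
  }
  u32 <- function(off) {
    sum(as.double(raw[off + 1:4]) * c(1, 256, 65536, 16777216))
  }
  if (u16(2) != 42) stop("bad TIFF magic in ", path)
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0) {
    n_tags <- u16(ifd)
    tags <- list()
    for (t in seq_len(n_tags)) {
      base <- ifd + 2 + (t - 1) * 12
      tag <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
      tsz <- if (type >= 1 && type <= 12) TIFF_TYPE_SIZES[type] else 1
      nbytes <- tsz * count
      voff <- if (nbytes > 4) u32(base + 8) else base + 8
      vals <- if (type == 3) {
        vapply(seq_len(count), function(k) u16(voff + (k - 1) * 2), numeric(1))
      } else if (type == 4) {
        vapply(seq_len(count), function(k) u32(voff + (k - 1) * 4), numeric(1))
      } else {
        NULL # types we do not need (ASCII, RATIONAL, ...) are skipped
      }
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop("required TIFF tag ", tag, " missing")
        default
      } else v
    }
    width <- need(256); height <- need(257)
    bits <- need(258, 1)[1]
    if (need(259, 1)[1] != 1) stop("compressed TIFF not supported")
    if (need(277, 1)[1] != 1) stop("only single-sample (grayscale) TIFF supported")
    fmt <- need(339, 1)[1]
    offs <- need(273); cnts <- need(279)
    buf <- raw(0)
    for (s in seq_along(offs)) {
      buf <- c(buf, raw[offs[s] + seq_len(cnts[s])])
    }
    v <- if (fmt == 3 && bits == 32) {
      readBin(buf, "numeric", n = width * height, size = 4, endian = "little")
    } else if (fmt == 1 && bits == 8) {
      as.numeric(readBin(buf, "integer", n = width * height, size = 1,
                         signed = FALSE, endian = "little"))
    } else if (fmt == 1 && bits == 16) {
      as.numeric(readBin(buf, "integer", n = width * height, size = 2,
                         signed = FALSE, endian = "little"))
    } else {
      stop("unsupported sample format: bits=", bits, " format=", fmt)
    }
    pages[[length(pages) + 1L]] <- matrix(v, nrow = height, ncol = width,
                                          byrow = TRUE)
    ifd <- u32(ifd + 2 + n_tags * 12)
  }
  pages
}
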