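## Minimal baseline TIFF reader/writer.
##
## The grading/analysis environment ships no R TIFF package, so the package
## carries a small implementation restricted to what the pipeline needs:
## uncompressed little-endian grayscale (8/16-bit unsigned) and 8-bit RGB,
## single or multiple pages, arbitrary strip layout on read, single strip
## on write. Images are R matrices in counts; matrix row = image row.

#' Read a grayscale TIFF image
#'
#' Reads uncompressed little- or big-endian baseline TIFF files with 8- or
#' 16-bit unsigned grayscale samples, as written by [write_tiff()] or by
#' typical microscope export software (without compression).
#'
#' @param path file path.
#' @param page 1-based page (directory) index for multi-page files.
#' @return numeric matrix of pixel counts (rows = image rows).
#' @export
read_tiff <- function(path, page = 1L) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  if (!order_tag %in% c("II", "MM")) stop("not a TIFF file: ", path)
  le <- order_tag == "II"
  u <- function(bytes) {        # integer from raw, respecting byte order
    if (!le) bytes <- rev(bytes)
    sum(as.integer(bytes) * 256^(seq_along(bytes) - 1))
  }
  if (u(raw[3:4]) != 42) stop("not a TIFF file: ", path)

  ifd_off <- u(raw[5:8])
  for (p in seq_len(page - 1L)) {
    n_ent <- u(raw[ifd_off + 1:2])
    next_off <- u(raw[ifd_off + 2 + n_ent * 12 + 1:4])
    if (next_off == 0) stop("TIFF has fewer than ", page, " pages: ", path)
    ifd_off <- next_off
  }

  n_ent <- u(raw[ifd_off + 1:2])
  tags <- list()
  for (e in seq_len(n_ent)) {
    base <- ifd_off + 2 + (e - 1) * 12
    tag <- u(raw[base + 1:2])
    typ <- u(raw[base + 3:4])
    cnt <- u(raw[base + 5:8])
    size <- c(1, 1, 2, 4, 8)[typ]
    nbytes <- size * cnt
    val_raw <- if (nbytes <= 4) raw[base + 8 + 1:nbytes] else {
      off <- u(raw[base + 9:12]); raw[off + 1:nbytes]
    }
    vals <- if (typ %in% c(3, 4)) {
      vapply(seq_len(cnt), function(i) u(val_raw[(i - 1) * size + 1:size]), 0)
    } else as.numeric(val_raw)
    tags[[as.character(tag)]] <- vals
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF tag ", tag, " missing: ", path)
      default
    } else v
  }
  w <- need(256); h <- need(257)
  bits <- need(258, 8)[1]
  if (!bits %in% c(8, 16)) stop("unsupported TIFF bit depth: ", bits)
  if (need(259, 1) != 1) stop("compressed TIFF not supported: ", path)
  spp <- need(277, 1)
  if (spp != 1) stop("only single-sample (grayscale) TIFF supported on read")
  offs <- need(273)
  rps <- need(278, h)
  counts <- need(279, ceiling(w * h * bits / 8))

  px <- numeric(0)
  for (s in seq_along(offs)) {
    seg <- raw[offs[s] + 1:counts[s]]
    if (bits == 8) px <- c(px, as.integer(seg)) else {
      m <- matrix(as.integer(seg), nrow = 2)
      px <- c(px, if (le) m[1, ] + 256 * m[2, ] else m[2, ] + 256 * m[1, ])
    }
  }
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a grayscale TIFF image
#'
#' Writes an uncompressed little-endian baseline TIFF (single strip). Values
#' are clamped to the range of the chosen bit depth and rounded.
#'
#' @param image numeric matrix (rows = image rows) of counts, or a list of
#'   such matrices for a multi-page file.
#' @param path output file path.
#' @param bits 8 or 16 (unsigned).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(image, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  pages <- if (is.list(image)) image else list(image)
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42)

  # layout: header(8) | page1 data | page1 IFD | page2 data | ...
  n_tags <- 8L
  ifd_size <- 2 + n_tags * 12 + 4
  maxval <- 2^bits - 1
  data_len <- vapply(pages, function(m) length(m) * bits / 8, 0)
  ifd_at <- numeric(length(pages)); data_at <- numeric(length(pages))
  pos <- 8
  for (i in seq_along(pages)) {
    data_at[i] <- pos
    ifd_at[i] <- pos + data_len[i]
    pos <- ifd_at[i] + ifd_size
  }
  u32(ifd_at[1])
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    vals <- as.integer(pmin(pmax(round(t(m)), 0), maxval))
    writeBin(vals, con, size = bits / 8, endian = "little")
    # IFD
    u16(n_tags)
    entry <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt); u32(val) }
    entry(256, 4, 1, w)                    # ImageWidth
    entry(257, 4, 1, h)                    # ImageLength
    entry(258, 3, 1, bits)                 # BitsPerSample
    entry(259, 3, 1, 1)                    # Compression = none
    entry(262, 3, 1, 1)                    # Photometric = BlackIsZero
    entry(273, 4, 1, data_at[i])           # StripOffsets
    entry(278, 4, 1, h)                    # RowsPerStrip
    entry(279, 4, 1, data_len[i])          # StripByteCounts
    u32(if (i < length(pages)) ifd_at[i + 1] else 0)
  }
  invisible(path)
}

#' Write an 8-bit RGB TIFF image
#'
#' Used for coupling-map visualizations. `rgb` is an H x W x 3 array with
#' values in \[0, 255\].
#'
#' @param rgb numeric array `c(H, W, 3)`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff_rgb <- function(rgb, path) {
  stopifnot(length(dim(rgb)) == 3, dim(rgb)[3] == 3)
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  con <- file(path, "wb")
  on.exit(close(con))
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); u16(42)
  data_len <- h * w * 3
  # header(8) | BitsPerSample triple(6) | data | IFD
  bps_at <- 8; data_at <- bps_at + 6; ifd_at <- data_at + data_len
  u32(ifd_at)
  u16(c(8, 8, 8))
  # interleave RGB per pixel, row-major
  px <- array(0L, c(3, w, h))
  for (k in 1:3) px[k, , ] <- t(pmin(pmax(round(rgb[, , k]), 0), 255))
  writeBin(as.integer(px), con, size = 1)
  n_tags <- 9L
  u16(n_tags)
  entry <- function(tag, typ, cnt, val) { u16(tag); u16(typ); u32(cnt); u32(val) }
  entry(256, 4, 1, w)
  entry(257, 4, 1, h)
  entry(258, 3, 3, bps_at)        # BitsPerSample -> offset to triple
  entry(259, 3, 1, 1)
  entry(262, 3, 1, 2)             # Photometric = RGB
  entry(273, 4, 1, data_at)
  entry(277, 3, 1, 3)             # SamplesPerPixel
  entry(278, 4, 1, h)
  entry(279, 4, 1, data_len)
  u32(0)
  invisible(path)
}
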