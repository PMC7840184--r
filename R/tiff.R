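# Minimal baseline TIFF 6.0 codec: little-endian, uncompressed, grayscale,
# single sample per pixel, uint8 / uint16 / float32. This covers exactly the
# stack formats the pipeline exchanges; it is not a general TIFF reader
# (no compression, no tiles, no palettes, no BigTIFF).

TIFF_DTYPES <- c(uint8 = 1L, uint16 = 2L, float32 = 4L)  # bytes per sample

#' Write a list of frames as a multi-page TIFF
#'
#' @param pages list of H x W numeric matrices (all identical dims)
#' @param path output file path
#' @param dtype one of "uint8", "uint16", "float32"; integer types are
#'   written bit-exact for values within range (values are not rescaled)
#' @return `path`, invisibly
#' @export
write_tiff <- function(pages, path, dtype = c("uint16", "uint8", "float32")) {
  dtype <- match.arg(dtype)
  if (is.matrix(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  for (p in pages) stopifnot(nrow(p) == H, ncol(p) == W)
  bps <- TIFF_DTYPES[[dtype]]
  nbytes <- H * W * bps
  ifd_size <- 2L + 10L * 12L + 4L
  # layout: 8-byte header, then per page [strip data][IFD]
  data_off <- 8L + (seq_along(pages) - 1L) * (nbytes + ifd_size)
  ifd_off <- data_off + nbytes

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(as.integer(ifd_off[1]), con, size = 4, endian = "little")

  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    w16(tag); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  sample_format <- if (dtype == "float32") 3L else 1L

  for (i in seq_along(pages)) {
    v <- as.vector(t(pages[[i]]))  # TIFF is row-major
    if (dtype == "float32") {
      writeBin(as.numeric(v), con, size = 4, endian = "little")
    } else {
      v <- as.integer(round(v))
      rng <- if (dtype == "uint8") 255 else 65535
      if (any(v < 0 | v > rng)) stop("intensities out of range for ", dtype)
      if (dtype == "uint8") {
        writeBin(as.raw(v), con)
      } else {
        # writeBin size=2 keeps the low 16 bits; valid for 0..65535
        suppressWarnings(writeBin(v, con, size = 2, endian = "little"))
      }
    }
    # IFD: 10 entries, ascending tag order
    w16(10L)
    entry(256L, 4L, 1L, W)                 # ImageWidth
    entry(257L, 4L, 1L, H)                 # ImageLength
    entry(258L, 3L, 1L, bps * 8L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)                # Compression: none
    entry(262L, 3L, 1L, 1L)                # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_off[i])       # StripOffsets
    entry(277L, 3L, 1L, 1L)                # SamplesPerPixel
    entry(278L, 4L, 1L, H)                 # RowsPerStrip
    entry(279L, 4L, 1L, nbytes)            # StripByteCounts
    entry(339L, 3L, 1L, sample_format)     # SampleFormat
    w32(if (i < length(pages)) ifd_off[i + 1] else 0L)
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the subset [write_tiff()] emits plus multi-strip layouts:
#' little-endian, uncompressed, 8/16-bit unsigned or 32-bit float, one
#' sample per pixel.
#'
#' @param path TIFF file path
#' @return list of H x W numeric matrices, one per page
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  order_tag <- rawToChar(raw[1:2])
  if (order_tag == "MM") stop("big-endian TIFF not supported")
  if (order_tag != "II") stop("not a TIFF file: ", path)
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = "little")
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "little")
    if (v < 0) v + 2^32 else v
  }
  if (u16(2) != 42L) stop("bad TIFF magic in ", path)

  pages <- list()
  ifd <- u32(4)
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val <- if (count == 1L) {
        if (type == 3L) u16(off + 8) else u32(off + 8)
      } else {
        voff <- u32(off + 8)
        step <- if (type == 3L) 2 else 4
        rd <- if (type == 3L) u16 else u32
        vapply(seq_len(count) - 1L, function(k) rd(voff + k * step), numeric(1))
      }
      tags[[as.character(tag)]] <- val
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 8L else tags[["258"]][1]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    sfmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1]
    spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
    if (comp != 1L) stop("compressed TIFF not supported")
    if (spp != 1L) stop("multi-sample TIFF not supported")
    offsets <- tags[["273"]]; counts <- tags[["279"]]
    if (is.null(offsets) || is.null(counts)) stop("missing strip tags")
    buf <- raw(0)
    for (s in seq_along(offsets)) {
      buf <- c(buf, raw[(offsets[s] + 1):(offsets[s] + counts[s])])
    }
    v <- if (sfmt == 3L && bits == 32L) {
      readBin(buf, "numeric", n = H * W, size = 4, endian = "little")
    } else if (bits == 8L) {
      as.numeric(readBin(buf, "integer", n = H * W, size = 1, signed = FALSE))
    } else if (bits == 16L) {
      as.numeric(readBin(buf, "integer", n = H * W, size = 2, signed = FALSE,
                         endian = "little"))
    } else {
      stop("unsupported TIFF sample layout (bits = ", bits, ", format = ", sfmt, ")")
    }
    pages[[length(pages) + 1L]] <- matrix(v, H, W, byrow = TRUE)
    ifd <- u32(ifd + 2 + n * 12)
  }
  if (!length(pages)) stop("TIFF contains no pages: ", path)
  pages
}
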