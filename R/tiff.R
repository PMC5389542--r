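#' Read a single-channel grayscale TIFF
#'
#' Minimal baseline-TIFF reader: uncompressed, single-sample (grayscale),
#' 8- or 16-bit, little- or big-endian, one or more strips. This covers the
#' files written by [write_tiff()] and by common microscopy exporters saving
#' raw 16-bit frames. Anything fancier (compression, tiles, RGB) is
#' rejected with an informative error.
#'
#' @param path Path to a TIFF file.
#' @return An integer matrix of pixel intensities with attribute
#'   `bit_depth` (8 or 16). Row `i`, column `j` of the matrix is image row
#'   `i`, column `j`.
#' @seealso [write_tiff()]
#' @export
read_tiff <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  endian <- if (identical(as.integer(magic), c(0x49L, 0x49L))) "little"
  else if (identical(as.integer(magic), c(0x4dL, 0x4dL))) "big"
  else stop("not a TIFF file: ", path)
  fortytwo <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  if (fortytwo != 42L) stop("not a TIFF file: ", path)
  ifd_off <- readBin(con, "integer", 1, size = 4, endian = endian)
  seek(con, ifd_off)
  n_entries <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
  tags <- list()
  for (i in seq_len(n_entries)) {
    tag <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    type <- readBin(con, "integer", 1, size = 2, signed = FALSE, endian = endian)
    count <- readBin(con, "integer", 1, size = 4, endian = endian)
    val_raw <- readBin(con, "raw", 4)
    tags[[as.character(tag)]] <- list(type = type, count = count, raw = val_raw)
  }
  rd_vals <- function(entry) {
    size <- switch(as.character(entry$type), "1" = 1L, "3" = 2L, "4" = 4L,
                   stop("unsupported TIFF tag type ", entry$type))
    total <- size * entry$count
    parse <- function(raw) {
      readBin(raw, "integer", n = entry$count, size = size,
              signed = size >= 4, endian = endian)
    }
    if (total <= 4) {
      parse(entry$raw)
    } else {
      off <- readBin(entry$raw, "integer", 1, size = 4, endian = endian)
      cur <- seek(con)
      seek(con, off)
      out <- readBin(con, "integer", n = entry$count, size = size,
                     signed = size >= 4, endian = endian)
      seek(con, cur)
      out
    }
  }
  need <- function(tag, default = NULL) {
    e <- tags[[as.character(tag)]]
    if (is.null(e)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag)
      return(default)
    }
    rd_vals(e)
  }
  width <- need(256)
  height <- need(257)
  bits <- need(258, 1L)
  compression <- need(259, 1L)
  spp <- need(277, 1L)
  if (compression != 1L) stop("compressed TIFF not supported: ", path)
  if (spp != 1L) stop("only single-channel grayscale TIFF supported: ", path)
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF supported, got ", bits)
  offs <- need(273)
  counts <- need(279, (width * height * bits) %/% 8L)
  rows_per_strip <- need(278, height)
  px <- integer(0)
  for (i in seq_along(offs)) {
    seek(con, offs[i])
    n_px <- counts[i] %/% (bits %/% 8L)
    px <- c(px, readBin(con, "integer", n = n_px, size = bits %/% 8L,
                        signed = FALSE, endian = endian))
  }
  if (length(px) != width * height)
    stop("TIFF pixel count mismatch in ", path)
  img <- matrix(px, nrow = height, ncol = width, byrow = TRUE)
  attr(img, "bit_depth") <- as.integer(bits)
  img
}

#' Write a single-channel grayscale TIFF
#'
#' Writes an uncompressed, little-endian, single-strip baseline TIFF.
#' Intensities are clamped to the bit-depth range and rounded to integers.
#'
#' @param img Numeric matrix of intensities.
#' @param path Output file path.
#' @param bits Bits per sample, 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(img, path, bits = 16L) {
  stop_if_not_matrix(img)
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  maxv <- 2^bits - 1
  v <- round(as.numeric(t(img)))           # row-major pixel order
  v[v < 0] <- 0
  v[v > maxv] <- maxv
  nr <- nrow(img); nc <- ncol(img)
  bytes_per <- bits %/% 8L
  data_len <- length(v) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(as.raw(c(0x49, 0x49)), con)     # "II"
  wr16(42); wr32(8 + data_len)             # IFD after pixel data
  writeBin(as.integer(v), con, size = bytes_per, endian = "little")
  entries <- list(
    list(256, 4L, 1L, nc),                 # ImageWidth
    list(257, 4L, 1L, nr),                 # ImageLength
    list(258, 3L, 1L, bits),               # BitsPerSample
    list(259, 3L, 1L, 1L),                 # Compression = none
    list(262, 3L, 1L, 1L),                 # Photometric = BlackIsZero
    list(273, 4L, 1L, 8L),                 # StripOffsets
    list(277, 3L, 1L, 1L),                 # SamplesPerPixel
    list(278, 4L, 1L, nr),                 # RowsPerStrip
    list(279, 4L, 1L, data_len),           # StripByteCounts
    list(339, 3L, 1L, 1L)                  # SampleFormat = unsigned int
  )
  wr16(length(entries))
  for (e in entries) {
    wr16(e[[1]]); wr16(e[[2]]); wr32(e[[3]])
    if (e[[2]] == 3L) { wr16(e[[4]]); wr16(0L) } else wr32(e[[4]])
  }
  wr32(0L)                                  # no next IFD
  invisible(path)
}
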