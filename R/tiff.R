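# ---- Minimal multi-page TIFF I/O --------------------------------------------
#
# No TIFF reader ships with the pre-installed R stack, so the package carries
# a deliberately minimal reader/writer for the one flavor it needs:
# uncompressed, single-sample grayscale (8- or 16-bit), little-endian,
# multi-page. Enough to round-trip VOI stacks; anything fancier (compression,
# tiles, RGB) is rejected with a clear message.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L)

#' Write a VOI stack as a multi-page 16-bit TIFF
#'
#' Uncompressed grayscale, one page per tangential slice, little-endian.
#' Values are rounded and clamped to [0, 65535].
#'
#' @param stack a \code{\link{voi_stack}} (or plain list of matrices).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_tiff_stack <- function(stack, path) {
  slices <- if (inherits(stack, "voi_stack")) stack$slices else stack
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)                 # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  ifd_ptr_pos <- 4L
  writeBin(0L, con, size = 4, endian = "little") # first IFD offset, patched
  offset <- 8L
  patch <- function(at, value) {
    seek(con, at, rw = "write")
    writeBin(as.integer(value), con, size = 4, endian = "little")
    seek(con, 0, origin = "end", rw = "write")
  }
  for (s in slices) {
    nr <- nrow(s); nc <- ncol(s)
    vals <- as.integer(pmin(pmax(round(t(s)), 0), 65535))  # row-major
    data_off <- offset
    writeBin(vals, con, size = 2, endian = "little")
    nbytes <- 2L * length(vals)
    ifd_off <- data_off + nbytes
    patch(ifd_ptr_pos, ifd_off)
    entries <- list(
      c(TIFF_TAGS[["ImageWidth"]], 3L, 1L, nc),
      c(TIFF_TAGS[["ImageLength"]], 3L, 1L, nr),
      c(TIFF_TAGS[["BitsPerSample"]], 3L, 1L, 16L),
      c(TIFF_TAGS[["Compression"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["Photometric"]], 3L, 1L, 1L),  # BlackIsZero
      c(TIFF_TAGS[["StripOffsets"]], 4L, 1L, data_off),
      c(TIFF_TAGS[["SamplesPerPixel"]], 3L, 1L, 1L),
      c(TIFF_TAGS[["RowsPerStrip"]], 3L, 1L, nr),
      c(TIFF_TAGS[["StripByteCounts"]], 4L, 1L, nbytes))
    writeBin(length(entries), con, size = 2, endian = "little")
    for (e in entries) {
      writeBin(as.integer(e[1]), con, size = 2, endian = "little")
      writeBin(as.integer(e[2]), con, size = 2, endian = "little")
      writeBin(as.integer(e[3]), con, size = 4, endian = "little")
      if (e[2] == 3L) {  # SHORT: value left-justified in 4-byte field
        writeBin(as.integer(e[4]), con, size = 2, endian = "little")
        writeBin(0L, con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(e[4]), con, size = 4, endian = "little")
      }
    }
    ifd_ptr_pos <- ifd_off + 2L + 12L * length(entries)
    writeBin(0L, con, size = 4, endian = "little")  # next-IFD, patched or 0
    offset <- ifd_ptr_pos + 4L
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF into a list of matrices
#'
#' Supports the subset \code{\link{write_tiff_stack}} produces: uncompressed,
#' grayscale, 8- or 16-bit, little- or big-endian, strip-organized.
#'
#' @param path TIFF file.
#' @return list of numeric matrices (one per page).
#' @export
read_tiff_stack <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: bad byte-order mark")
  u16 <- function(off) readBin(raw[(off + 1):(off + 2)], "integer", size = 2,
                               signed = FALSE, endian = endian)
  u32 <- function(off) {
    v <- readBin(raw[(off + 1):(off + 4)], "integer", size = 4,
                 endian = endian)
    if (v < 0) stop("TIFF offsets beyond 2 GiB are not supported")
    v
  }
  if (u16(2) != 42L) stop("not a TIFF file: bad magic number")
  ifd <- u32(4)
  pages <- list()
  while (ifd != 0L) {
    n_entries <- u16(ifd)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd + 2L + 12L * (i - 1L)
      tag <- u16(e); type <- u16(e + 2L); count <- u32(e + 4L)
      if (count != 1L && tag %in% TIFF_TAGS[c("StripOffsets",
                                              "StripByteCounts")])
        stop("multi-strip TIFF not supported (single strip per page only)")
      value <- if (type == 3L) u16(e + 8L) else u32(e + 8L)
      tags[[as.character(tag)]] <- value
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(TIFF_TAGS[[tag]])]]
      if (is.null(v)) default else v
    }
    if (g("Compression", 1L) != 1L)
      stop("compressed TIFF not supported (uncompressed grayscale only)")
    if (g("SamplesPerPixel", 1L) != 1L)
      stop("multi-sample (color) TIFF not supported")
    bits <- g("BitsPerSample", 1L)
    if (!bits %in% c(8L, 16L))
      stop("only 8- and 16-bit grayscale TIFF supported")
    nc <- g("ImageWidth"); nr <- g("ImageLength")
    off <- g("StripOffsets")
    nbytes <- g("StripByteCounts", nr * nc * bits / 8L)
    if (is.null(nc) || is.null(nr) || is.null(off))
      stop("malformed TIFF: missing required tags")
    vals <- readBin(raw[(off + 1):(off + nbytes)], "integer",
                    n = nr * nc, size = bits / 8L, signed = FALSE,
                    endian = endian)
    pages[[length(pages) + 1L]] <- t(matrix(vals, nc, nr))  # row-major data
    ifd <- u32(ifd + 2L + 12L * n_entries)
  }
  pages
}
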