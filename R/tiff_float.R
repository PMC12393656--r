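#' Write a single-channel 32-bit float TIFF
#'
#' Minimal uncompressed little-endian TIFF writer storing IEEE float samples
#' as-is (including negative values, which integer-scaled writers cannot
#' represent). The pixel size is recorded in the X/Y resolution tags
#' (pixels per centimeter). The matrix's first dimension is written as image
#' rows.
#'
#' @param img Numeric matrix.
#' @param path Output path.
#' @param pixel_size_mm Pixel spacing recorded in the resolution tags.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(img, path, pixel_size_mm = 1) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  h <- nrow(img); w <- ncol(img)
  data_bytes <- 4L * h * w
  n_tags <- 13L
  data_off <- 8L
  ifd_off <- data_off + data_bytes
  rat_off <- ifd_off + 2L + n_tags * 12L + 4L
  px_per_cm <- round(10 / pixel_size_mm * 1000)  # rational: n / 1000

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(c(42L, 0L), con, size = 1)             # magic 42, little-endian
  writeBin(as.integer(ifd_off), con, size = 4, endian = "little")
  writeBin(as.numeric(t(img)), con, size = 4, endian = "little")

  tag <- function(id, type, count, value) {
    writeBin(as.integer(c(id, type)), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    if (type == 3 && count == 1) {                # SHORT packed left
      writeBin(as.integer(value), con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(as.integer(value), con, size = 4, endian = "little")
    }
  }
  writeBin(n_tags, con, size = 2, endian = "little")
  tag(256, 4, 1, w)                # ImageWidth
  tag(257, 4, 1, h)                # ImageLength
  tag(258, 3, 1, 32)               # BitsPerSample
  tag(259, 3, 1, 1)                # Compression: none
  tag(262, 3, 1, 1)                # Photometric: BlackIsZero
  tag(273, 4, 1, data_off)         # StripOffsets
  tag(277, 3, 1, 1)                # SamplesPerPixel
  tag(278, 4, 1, h)                # RowsPerStrip
  tag(279, 4, 1, data_bytes)       # StripByteCounts
  tag(282, 5, 1, rat_off)          # XResolution -> rational
  tag(283, 5, 1, rat_off + 8L)     # YResolution
  tag(296, 3, 1, 3)                # ResolutionUnit: cm
  tag(339, 3, 1, 3)                # SampleFormat: IEEE float
  writeBin(0L, con, size = 4, endian = "little")  # next IFD: none
  writeBin(as.integer(c(px_per_cm, 1000, px_per_cm, 1000)), con,
           size = 4, endian = "little")
  invisible(path)
}
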