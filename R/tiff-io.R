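# Minimal baseline TIFF support: single-channel, 16-bit, uncompressed.
# No TIFF package ships with the target R stack, so the two functions below
# implement exactly the subset this package writes (and read back both
# single- and multi-strip uncompressed grayscale files).

#' Write a 16-bit grayscale TIFF
#'
#' Baseline little-endian uncompressed TIFF, one strip, photometric
#' min-is-black.  Values are rounded and clamped to \[0, 65535\].
#'
#' @param img numeric matrix; rows are image rows.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tiff16 <- function(img, path) {
  stopifnot(is.matrix(img), is.numeric(img))
  h <- nrow(img); w <- ncol(img)
  px <- as.integer(pmin(pmax(round(img), 0), 65535))
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con)              # little-endian byte order
  w16(42L)                                    # TIFF magic
  w32(8L)                                     # first IFD offset
  ntags <- 10L
  data_off <- 8L + 2L + ntags * 12L + 4L
  tag <- function(id, type, count, value) {   # type 3 = SHORT, 4 = LONG
    w16(id); w16(type); w32(count)
    if (type == 3L) { w16(value); w16(0L) } else w32(value)
  }
  w16(ntags)
  tag(256L, 4L, 1L, w)                        # ImageWidth
  tag(257L, 4L, 1L, h)                        # ImageLength
  tag(258L, 3L, 1L, 16L)                      # BitsPerSample
  tag(259L, 3L, 1L, 1L)                       # Compression: none
  tag(262L, 3L, 1L, 1L)                       # Photometric: min-is-black
  tag(273L, 4L, 1L, data_off)                 # StripOffsets
  tag(277L, 3L, 1L, 1L)                       # SamplesPerPixel
  tag(278L, 4L, 1L, h)                        # RowsPerStrip
  tag(279L, 4L, 1L, 2L * w * h)               # StripByteCounts
  tag(339L, 3L, 1L, 1L)                       # SampleFormat: unsigned int
  w32(0L)                                     # no further IFD
  # pixel data, row-major; writeBin truncates 32-bit ints to the low 16 bits,
  # which is exactly the unsigned encoding for values in [0, 65535]
  writeBin(as.integer(t(img_clamp(px, h, w))), con, size = 2,
           endian = "little")
  invisible(path)
}

img_clamp <- function(px, h, w) matrix(px, nrow = h, ncol = w)

#' Read a 16-bit grayscale TIFF
#'
#' Reads uncompressed single-sample 16-bit grayscale baseline TIFFs (either
#' byte order, one or more strips) such as those produced by
#' [write_tiff16()].
#'
#' @param path TIFF file path.
#' @return Numeric matrix of pixel values.
#' @export
read_tiff16 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2))
  endian <- switch(order_bytes, II = "little", MM = "big",
                   stop_mixcount("not a TIFF file: %s", path,
                                 class = "mixcount_tiff_error"))
  r16 <- function(n = 1) readBin(con, "integer", n, size = 2, signed = FALSE,
                                 endian = endian)
  r32 <- function(n = 1) readBin(con, "integer", n, size = 4, endian = endian)
  if (r16() != 42L)
    stop_mixcount("bad TIFF magic in %s", path, class = "mixcount_tiff_error")
  ifd_off <- r32()
  seek(con, ifd_off)
  ntags <- r16()
  tags <- list()
  for (i in seq_len(ntags)) {
    id <- r16(); type <- r16(); count <- r32()
    raw4 <- readBin(con, "raw", 4)
    tags[[as.character(id)]] <- list(type = type, count = count, raw = raw4)
  }
  val <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) return(default)
    inline_n <- if (t$type == 3L) 2L else 1L
    rcon <- rawConnection(t$raw)
    on.exit(close(rcon), add = TRUE)
    rd <- function(cn) {
      if (t$type == 3L) readBin(cn, "integer", t$count, size = 2,
                                signed = FALSE, endian = endian)
      else readBin(cn, "integer", t$count, size = 4, endian = endian)
    }
    if (t$count <= inline_n) rd(rcon)
    else {
      off <- readBin(rcon, "integer", 1, size = 4, endian = endian)
      seek(con, off)
      rd(con)
    }
  }
  w <- val(256L); h <- val(257L)
  bits <- val(258L, 1L); comp <- val(259L, 1L); spp <- val(277L, 1L)
  if (is.null(w) || is.null(h))
    stop_mixcount("TIFF missing dimensions: %s", path,
                  class = "mixcount_tiff_error")
  if (comp != 1L || bits[1] != 16L || spp != 1L)
    stop_mixcount(paste0("unsupported TIFF (need uncompressed 16-bit ",
                         "grayscale): %s"), path, class = "mixcount_tiff_error")
  offsets <- val(273L)
  counts <- val(279L, 2L * w * h)
  px <- integer(0)
  for (s in seq_along(offsets)) {
    seek(con, offsets[s])
    px <- c(px, readBin(con, "integer", counts[s] / 2L, size = 2,
                        signed = FALSE, endian = endian))
  }
  if (length(px) != w * h)
    stop_mixcount("truncated TIFF pixel data: %s", path,
                  class = "mixcount_tiff_error")
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}
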