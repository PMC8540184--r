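# Image and mask file I/O.
#
# The canonical on-disk format is the 8-bit uncompressed BMP bitmap (the
# clinical source data were 512x512 bitmaps, and BMP round-trips literal
# 0-255 values losslessly without any codec dependency). Masks store literal
# label values 0..3; images store intensities scaled to 0..255.

u16 <- function(con, x = NULL) {
  if (is.null(x)) return(readBin(con, "integer", 1, size = 2, signed = FALSE,
                                 endian = "little"))
  writeBin(as.integer(x), con, size = 2, endian = "little")
}
u32 <- function(con, x = NULL) {
  if (is.null(x)) return(readBin(con, "integer", 1, size = 4,
                                 endian = "little"))
  writeBin(as.integer(x), con, size = 4, endian = "little")
}

write_bmp8 <- function(values, path) {
  stopifnot(is.matrix(values))
  v <- as.integer(round(values))
  assert_that(all(v >= 0 & v <= 255), "write_bmp8: values outside 0..255",
              "discseg_io_error")
  H <- nrow(values); W <- ncol(values)
  pad <- (4 - W %% 4) %% 4
  data_offset <- 14L + 40L + 256L * 4L
  file_size <- data_offset + (W + pad) * H
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(con, file_size); u32(con, 0L); u32(con, data_offset)
  u32(con, 40L); u32(con, W); u32(con, H)
  u16(con, 1L); u16(con, 8L)
  u32(con, 0L); u32(con, (W + pad) * H)
  u32(con, 2835L); u32(con, 2835L); u32(con, 256L); u32(con, 0L)
  pal <- as.raw(rbind(0:255, 0:255, 0:255, rep(0L, 256)))
  writeBin(pal, con)
  m <- matrix(v, H, W)
  rowpad <- as.raw(rep(0L, pad))
  for (r in H:1) {                      # BMP stores rows bottom-up
    writeBin(c(as.raw(m[r, ]), rowpad), con)
  }
  invisible(path)
}

read_bmp8 <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path),
              "discseg_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) {
    abort_discseg(paste("not a BMP image:", path), "discseg_io_error")
  }
  u32(con); u32(con)
  data_offset <- u32(con)
  header_size <- u32(con)
  assert_that(header_size >= 40, paste("unsupported BMP header in", path),
              "discseg_io_error")
  W <- u32(con); H_raw <- u32(con)
  top_down <- H_raw < 0
  H <- abs(H_raw)
  u16(con)
  bitcount <- u16(con)
  if (bitcount != 8) {
    abort_discseg(sprintf(
      "%s: only 8-bit grayscale BMP is supported (found %d-bit)",
      path, bitcount), "discseg_io_error")
  }
  compression <- u32(con)
  assert_that(compression == 0,
              paste("compressed BMP not supported:", path), "discseg_io_error")
  seek(con, data_offset)
  pad <- (4 - W %% 4) %% 4
  m <- matrix(0L, H, W)
  rows <- if (top_down) 1:H else H:1
  for (r in rows) {
    m[r, ] <- as.integer(readBin(con, "raw", W))
    if (pad > 0) readBin(con, "raw", pad)
  }
  m
}

#' Read / write grayscale images and label masks
#'
#' Images are stored as 8-bit BMP with intensities scaled to 0..255 and read
#' back into \[0, 1\]; masks store literal integer label values and
#' round-trip losslessly.
#'
#' @param path file path.
#' @param image matrix in \[0, 1\].
#' @param mask integer matrix of labels in 0..255.
#' @return `read_image`: matrix in \[0, 1\]; `read_mask`: integer matrix.
#' @export
read_image <- function(path) {
  read_bmp8(path) / 255
}

#' @rdname read_image
#' @export
write_image <- function(image, path) {
  write_bmp8(clamp01(image) * 255, path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  read_bmp8(path)
}

#' @rdname read_image
#' @export
write_mask <- function(mask, path) {
  write_bmp8(mask, path)
}

#' Write a stage-2 input as an RGB composite (debug aid)
#'
#' Maps the fused channels (image, distance-to-disc-2, distance-to-disc-3)
#' to R, G, B of a 24-bit BMP.
#'
#' @param fused `H x W x 3` array from [fuse_channels()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_rgb_composite <- function(fused, path) {
  stopifnot(length(dim(fused)) == 3, dim(fused)[3] == 3)
  H <- dim(fused)[1]; W <- dim(fused)[2]
  v <- round(clamp01(fused) * 255)
  pad <- (4 - (W * 3) %% 4) %% 4
  data_offset <- 14L + 40L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(con, data_offset + (W * 3 + pad) * H); u32(con, 0L); u32(con, data_offset)
  u32(con, 40L); u32(con, W); u32(con, H)
  u16(con, 1L); u16(con, 24L)
  u32(con, 0L); u32(con, (W * 3 + pad) * H)
  u32(con, 2835L); u32(con, 2835L); u32(con, 0L); u32(con, 0L)
  rowpad <- as.raw(rep(0L, pad))
  for (r in H:1) {
    bgr <- as.raw(rbind(v[r, , 3], v[r, , 2], v[r, , 1]))
    writeBin(c(bgr, rowpad), con)
  }
  invisible(path)
}
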