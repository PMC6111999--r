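# Minimal codec for uncompressed 24-bit Windows BMP (BI_RGB), the format the
# PH2 dermoscopy archive ships. No installed package decodes BMP, so the two
# dozen lines live here. Top-down files (negative height) are handled; other
# bit depths or compressions raise a format error.

read_u16 <- function(raw, off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
read_u32 <- function(raw, off) {
  v <- as.integer(raw[off + 1:4])
  v[1] + 256 * v[2] + 65536 * v[3] + 16777216 * v[4]
}

read_bmp <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop_format("not a BMP file")
  data_off <- read_u32(raw, 10)
  w <- read_u32(raw, 18)
  h_raw <- read_u32(raw, 22)
  top_down <- h_raw > 2^31 - 1
  h <- if (top_down) 2^32 - h_raw else h_raw
  bpp <- read_u16(raw, 28)
  compression <- read_u32(raw, 30)
  if (bpp != 24 || compression != 0)
    stop_format("only uncompressed 24-bit BMP is supported")
  stride <- ((w * 3 + 3) %/% 4) * 4
  if (length(raw) < data_off + stride * h) stop_format("truncated BMP file")
  out <- array(0, dim = c(h, w, 3L))
  px <- as.integer(raw[data_off + seq_len(stride * h)])
  rows <- matrix(px, nrow = stride)[seq_len(w * 3), , drop = FALSE]
  # file rows are bottom-up unless top_down; pixels are B,G,R
  b <- t(rows[seq(1, w * 3, by = 3), , drop = FALSE])
  g <- t(rows[seq(2, w * 3, by = 3), , drop = FALSE])
  r <- t(rows[seq(3, w * 3, by = 3), , drop = FALSE])
  ord <- if (top_down) seq_len(h) else rev(seq_len(h))
  out[, , 1] <- r[ord, , drop = FALSE]
  out[, , 2] <- g[ord, , drop = FALSE]
  out[, , 3] <- b[ord, , drop = FALSE]
  out
}

write_bmp <- function(img, path) {
  img <- as_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  stride <- ((w * 3 + 3) %/% 4) * 4
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(54 + stride * h); u32(0); u32(54)          # file size, reserved, data offset
  u32(40); u32(w); u32(h); u16(1); u16(24)       # info header
  u32(0); u32(stride * h); u32(2835); u32(2835); u32(0); u32(0)
  pad <- as.raw(rep(0, stride - w * 3))
  for (row in rev(seq_len(h))) {
    bgr <- rbind(img[row, , 3], img[row, , 2], img[row, , 1])
    writeBin(as.raw(as.integer(bgr)), con)
    if (length(pad)) writeBin(pad, con)
  }
  invisible(path)
}
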