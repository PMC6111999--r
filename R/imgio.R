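#' Image containers
#'
#' Colour images are plain numeric arrays of dimension `h x w x 3` holding
#' integer channel values in `[0, 255]` (R, G, B planes); grayscale images are
#' `h x w` matrices on the same scale. Pixel `(x, y)` means column `x`,
#' row `y`, origin top-left, so a pixel is addressed as `img[y, x, ]`.
#'
#' @param pixels numeric array (`h x w x 3`) or matrix (`h x w`).
#' @return The validated array/matrix, unchanged.
#' @name image-containers
NULL

#' @rdname image-containers
#' @export
as_rgb_image <- function(pixels) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop_domain("an RGB image must be an h x w x 3 array")
  if (any(pixels < 0 | pixels > 255) || anyNA(pixels))
    stop_domain("channel values must lie in [0, 255]")
  pixels
}

#' @rdname image-containers
#' @export
as_gray_image <- function(pixels) {
  if (!is.matrix(pixels)) stop_domain("a gray image must be an h x w matrix")
  if (any(pixels < 0 | pixels > 255) || anyNA(pixels))
    stop_domain("gray values must lie in [0, 255]")
  pixels
}

img_width <- function(img) dim(img)[2]
img_height <- function(img) dim(img)[1]

#' Load an image file as an RGB array
#'
#' Reads PNG, JPEG or uncompressed 24-bit BMP. An alpha channel is discarded;
#' grayscale files are replicated across the three channels.
#'
#' @param path file path.
#' @return An `h x w x 3` array of integers in `[0, 255]`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop_format(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = {
      raw <- tryCatch(png::readPNG(path),
                      error = function(e) stop_format(paste0("cannot decode PNG: ", conditionMessage(e))))
      round_half_up(255 * raw)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop_format("JPEG support requires the EBImage package")
      raw <- tryCatch(EBImage::imageData(EBImage::readImage(path)),
                      error = function(e) stop_format(paste0("cannot decode JPEG: ", conditionMessage(e))))
      # EBImage stores width-major planes; transpose to row-major
      raw <- if (length(dim(raw)) == 2L) t(raw) else aperm(raw, c(2, 1, 3))
      round_half_up(255 * raw)
    },
    bmp = read_bmp(path),
    stop_format(paste0("unsupported image format: .", ext))
  )
  if (is.matrix(arr)) arr <- array(rep(arr, 3L), dim = c(dim(arr), 3L))
  if (dim(arr)[3] > 3L) arr <- arr[, , 1:3, drop = FALSE]
  if (dim(arr)[3] == 2L) arr <- array(rep(arr[, , 1L], 3L), dim = c(dim(arr)[1:2], 3L))
  as_rgb_image(clamp255(arr))
}

#' Save an RGB image
#'
#' Writes PNG (via the png package) or uncompressed 24-bit BMP.
#'
#' @param img `h x w x 3` array in `[0, 255]`.
#' @param path destination; format chosen by extension.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  img <- as_rgb_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img / 255, target = path),
    bmp = write_bmp(img, path),
    stop_format(paste0("unsupported output format: .", ext))
  )
  invisible(path)
}

#' Convert to grayscale by channel averaging
#'
#' Each output pixel is `floor((R + G + B) / 3)`.
#'
#' @param img `h x w x 3` array in `[0, 255]`.
#' @return `h x w` matrix in `[0, 255]`.
#' @export
to_gray <- function(img) {
  img <- as_rgb_image(img)
  g <- floor((img[, , 1] + img[, , 2] + img[, , 3]) / 3)
  if (!is.matrix(g)) g <- matrix(g, dim(img)[1], dim(img)[2])
  g
}

#' Gamma correction
#'
#' Maps each gray value `C` to `round(255 * (C/255)^gamma)` (round half up),
#' clamped to `[0, 255]`. `gamma = 1` is an exact identity.
#'
#' @param img gray matrix in `[0, 255]`.
#' @param gamma positive correction coefficient.
#' @return Gray matrix of the same dimensions.
#' @export
gamma_correct <- function(img, gamma) {
  img <- as_gray_image(img)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop_domain("gamma must be a single positive number")
  clamp255(round_half_up(255 * (img / 255)^gamma))
}

#' Contrast adjustment
#'
#' Applies the contrast stretch `F * (C - 128) + 128` with
#' `F = 259 (omega + 255) / (255 (259 - omega))`, rounded half up and clamped
#' to `[0, 255]`. `omega = 0` gives `F = 1`, an exact identity; 128 is a fixed
#' point for every `omega`.
#'
#' @param img gray matrix in `[0, 255]`.
#' @param omega contrast level in `[-255, 255]`.
#' @return Gray matrix of the same dimensions.
#' @export
adjust_contrast <- function(img, omega) {
  img <- as_gray_image(img)
  if (!is.numeric(omega) || length(omega) != 1L || omega < -255 || omega > 255)
    stop_domain("omega must be a single number in [-255, 255]")
  f <- 259 * (omega + 255) / (255 * (259 - omega))
  clamp255(round_half_up(f * (img - 128) + 128))
}

# 256-bin count vectors for gray, R, G, B — the internal fast path
hist_set <- function(img) {
  img <- as_rgb_image(img)
  g <- to_gray(img)
  count <- function(v) tabulate(as.integer(v) + 1L, nbins = 256L)
  list(gray = count(g), R = count(img[, , 1]), G = count(img[, , 2]),
       B = count(img[, , 3]))
}

#' Per-channel 256-bin histograms
#'
#' Returns counts for the gray (channel-averaged), R, G and B channels.
#' Each channel's counts sum to the pixel count of the image.
#'
#' @param img `h x w x 3` array in `[0, 255]`.
#' @return A tibble with columns `channel` (gray/R/G/B), `bin` (0-255) and
#'   `count`.
#' @export
histograms <- function(img) {
  hs <- hist_set(img)
  tibble(
    channel = rep(names(hs), each = 256L),
    bin = rep(0:255, times = 4L),
    count = unlist(hs, use.names = FALSE)
  )
}

# bilinear sample of one plane at target size, half-pixel centre alignment
bilinear_plane <- function(m, tw, th) {
  h <- nrow(m); w <- ncol(m)
  sx <- (seq_len(tw) - 0.5) * w / tw + 0.5
  sy <- (seq_len(th) - 0.5) * h / th + 0.5
  x0r <- floor(sx); fx <- sx - x0r
  y0r <- floor(sy); fy <- sy - y0r
  x0 <- pmin(pmax(x0r, 1), w); x1 <- pmin(pmax(x0r + 1, 1), w)
  y0 <- pmin(pmax(y0r, 1), h); y1 <- pmin(pmax(y0r + 1, 1), h)
  fxm <- matrix(fx, th, tw, byrow = TRUE)
  fym <- matrix(fy, th, tw)
  (1 - fym) * ((1 - fxm) * m[y0, x0, drop = FALSE] + fxm * m[y0, x1, drop = FALSE]) +
    fym * ((1 - fxm) * m[y1, x0, drop = FALSE] + fxm * m[y1, x1, drop = FALSE])
}

#' Bilinear resize
#'
#' Resizes an RGB or gray image to the requested dimensions with bilinear
#' interpolation (pixel-centre alignment, so resizing to the original size is
#' an exact identity).
#'
#' @param img RGB array or gray matrix in `[0, 255]`.
#' @param target_w,target_h output dimensions in pixels (>= 1).
#' @return Image of the same kind with dimensions `target_h x target_w`.
#' @export
resize_image <- function(img, target_w, target_h) {
  if (target_w < 1 || target_h < 1) stop_domain("target dimensions must be >= 1")
  if (is.matrix(img)) {
    return(clamp255(round_half_up(bilinear_plane(img, target_w, target_h))))
  }
  img <- as_rgb_image(img)
  out <- array(0, dim = c(target_h, target_w, 3L))
  for (c in 1:3) out[, , c] <- bilinear_plane(img[, , c], target_w, target_h)
  clamp255(round_half_up(out))
}
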