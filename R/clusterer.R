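#' Cluster extraction parameters
#'
#' @param window_frac crop window size as a fraction of the source image's
#'   width and height (the window is `ceil(window_frac * w)` by
#'   `ceil(window_frac * h)`).
#' @param reject_frac a key point is dropped when its same-colour region
#'   covers more than this fraction of the crop window (such a region is the
#'   surrounding skin or wall, not a compact mark).
#' @param gamma gamma-correction coefficient applied to the window.
#' @param omega contrast level applied after gamma correction.
#' @param color_tol intensity tolerance defining "the same colour" during
#'   region growth (on the processed grayscale window).
#' @param target_dim `c(width, height)` of the final uniform cluster image.
#' @param min_region minimum region pixel count; smaller regions are noise
#'   and are rejected.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(window_frac = 0.15, reject_frac = 0.30,
                           gamma = 1.2, omega = 64, color_tol = 10,
                           target_dim = c(64L, 64L), min_region = 9L) {
  stopifnot(window_frac > 0, window_frac < 1, reject_frac > 0, reject_frac < 1,
            all(target_dim >= 8), min_region >= 1)
  structure(list(window_frac = window_frac, reject_frac = reject_frac,
                 gamma = gamma, omega = omega, color_tol = color_tol,
                 target_dim = as.integer(target_dim),
                 min_region = as.integer(min_region)),
            class = "cluster_params")
}

#' Same-colour region growth
#'
#' The maximal 4-connected set of pixels containing the seed in which every
#' member's intensity is within `tol` of the seed intensity. Implemented
#' iteratively (explicit queue), so deep regions cannot exhaust the call
#' stack.
#'
#' @param img gray matrix.
#' @param seed_x,seed_y seed pixel (column, row), 1-based.
#' @param tol intensity tolerance relative to the seed.
#' @return A list of class `pixel_region`: logical `mask`, `size`, and
#'   `bbox = c(min_x, min_y, max_x, max_y)`.
#' @export
region_grow <- function(img, seed_x, seed_y, tol) {
  img <- as_gray_image(img)
  if (seed_x < 1 || seed_y < 1 || seed_x > ncol(img) || seed_y > nrow(img))
    stop_domain("seed outside image")
  mask <- flood_fill_cpp(img, as.integer(seed_y), as.integer(seed_x), tol)
  px <- which(mask, arr.ind = TRUE)
  structure(list(mask = mask, size = nrow(px),
                 bbox = c(min(px[, 2]), min(px[, 1]), max(px[, 2]), max(px[, 1]))),
            class = "pixel_region")
}

is_cluster_rejection <- function(x) inherits(x, "cluster_rejection")

reject_cluster <- function(reason) structure(list(reason = reason),
                                             class = "cluster_rejection")

#' Extract a normalized cluster image around one key point
#'
#' Pipeline per key point: (1) crop a `window_frac`-sized window centred on
#' the key point (clipped at borders); (2) convert the window to grayscale by
#' channel averaging; (3) gamma-correct; (4) stretch contrast — the two
#' steps flatten the window so a nevus becomes a near-uniform dark region;
#' (5) grow the same-colour region from the key point; (6) reject when the
#' region covers more than `reject_frac` of the window (no compact mark) or
#' fewer than `min_region` pixels (noise); (7) crop to the region bounding
#' box; (8) restore original colours over the cropped coordinates; (9)
#' resize to `target_dim`.
#'
#' @param img full RGB image.
#' @param kp one key-point row (needs `x`, `y`; `sigma`/`response` carried
#'   along when present).
#' @param params a [cluster_params()] list.
#' @return A list of class `dermo_cluster` (fields `image`, `source_keypoint`,
#'   `region_size`, `region_pixels` (linear indices into the full image),
#'   `bbox_full`, `state = "raw"`), or a `cluster_rejection` with a `reason`.
#' @export
extract_cluster <- function(img, kp, params = cluster_params()) {
  img <- as_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  kx <- round_half_up(kp$x[1]); ky <- round_half_up(kp$y[1])
  if (kx < 1 || ky < 1 || kx > w || ky > h) stop_domain("key point outside image")
  cw <- ceiling(params$window_frac * w); ch <- ceiling(params$window_frac * h)
  x0 <- min(max(kx - floor((cw - 1) / 2), 1), w - cw + 1)
  y0 <- min(max(ky - floor((ch - 1) / 2), 1), h - ch + 1)
  win <- img[y0:(y0 + ch - 1), x0:(x0 + cw - 1), , drop = FALSE]
  proc <- adjust_contrast(gamma_correct(to_gray(win), params$gamma), params$omega)
  sx <- kx - x0 + 1; sy <- ky - y0 + 1
  reg <- region_grow(proc, sx, sy, params$color_tol)
  if (reg$size > params$reject_frac * cw * ch)
    return(reject_cluster("region_too_large"))
  if (reg$size < params$min_region)
    return(reject_cluster("region_too_small"))
  bb <- reg$bbox
  crop <- win[bb[2]:bb[4], bb[1]:bb[3], , drop = FALSE]  # original colours
  out <- resize_image(crop, params$target_dim[1], params$target_dim[2])
  px <- which(reg$mask)
  win_rows <- ((px - 1) %% ch) + 1; win_cols <- ((px - 1) %/% ch) + 1
  full_idx <- (win_cols + x0 - 2) * h + (win_rows + y0 - 1)
  structure(list(
    image = out,
    source_keypoint = kp[1, intersect(names(kp), c("x", "y", "sigma",
                                                   "orientation", "response"))],
    region_size = reg$size,
    region_pixels = full_idx,
    bbox_full = c(bb[1] + x0 - 1, bb[2] + y0 - 1, bb[3] + x0 - 1, bb[4] + y0 - 1),
    state = "raw"
  ), class = "dermo_cluster")
}

#' Clusters for all key points of an image
#'
#' Applies [extract_cluster()] to every key point, drops rejections, and
#' deduplicates clusters whose regions overlap by more than 50% (of the
#' smaller region), keeping the one with the larger absolute detector
#' response.
#'
#' @param img full RGB image.
#' @param kps key-point tibble.
#' @param params a [cluster_params()] list.
#' @return List of `dermo_cluster` objects.
#' @export
clusters_from_image <- function(img, kps, params = cluster_params()) {
  if (nrow(kps) == 0) return(list())
  cl <- list()
  for (n in seq_len(nrow(kps))) {
    c_n <- extract_cluster(img, kps[n, ], params)
    if (!is_cluster_rejection(c_n)) cl[[length(cl) + 1]] <- c_n
  }
  if (length(cl) <= 1) return(cl)
  resp <- vapply(cl, function(c) {
    r <- c$source_keypoint$response
    if (is.null(r) || is.na(r)) 0 else abs(r)
  }, numeric(1))
  keep <- rep(TRUE, length(cl))
  ord <- order(-resp)   # strongest first; weaker duplicates dropped
  for (a in seq_along(ord)) {
    ia <- ord[a]
    if (!keep[ia]) next
    for (b in seq_along(ord)) {
      if (b <= a) next
      ib <- ord[b]
      if (!keep[ib]) next
      inter <- length(intersect(cl[[ia]]$region_pixels, cl[[ib]]$region_pixels))
      if (inter > 0.5 * min(cl[[ia]]$region_size, cl[[ib]]$region_size))
        keep[ib] <- FALSE
    }
  }
  cl[keep]
}
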