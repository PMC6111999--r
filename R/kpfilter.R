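#' Skin palette
#'
#' A small set of anchor colours with a per-channel tolerance; a key point is
#' considered on-palette when the median colour of its 3 x 3 neighbourhood is
#' within `tolerance` of at least one anchor in every channel. The shipped
#' default covers light-to-dark skin tones plus the brown shades of pigmented
#' nevi (off-palette points — clothing, jewellery, furnishings — are
#' filtered out before clustering).
#'
#' @param colors numeric matrix `n x 3` of (R, G, B) anchors in `[0, 255]`.
#' @param tolerance maximum per-channel distance (0-255).
#' @return A list of class `skin_palette`.
#' @export
skin_palette <- function(colors, tolerance = 40) {
  colors <- matrix(as.numeric(colors), ncol = 3)
  if (nrow(colors) < 1) stop_domain("palette needs at least one anchor")
  if (tolerance < 0 || tolerance > 255) stop_domain("tolerance must be in [0, 255]")
  structure(list(colors = colors, tolerance = tolerance), class = "skin_palette")
}

#' @rdname skin_palette
#' @export
default_skin_palette <- function() {
  path <- system.file("extdata", "skin_palette.json", package = "dermoscan")
  read_skin_palette(path)
}

#' @rdname skin_palette
#' @param path JSON file path.
#' @export
read_skin_palette <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  skin_palette(as.matrix(j$colors), j$tolerance)
}

#' @rdname skin_palette
#' @param palette a `skin_palette`.
#' @export
write_skin_palette <- function(palette, path) {
  jsonlite::write_json(list(colors = unname(palette$colors),
                            tolerance = palette$tolerance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Background key-point reference
#'
#' Detects key points in one or more reference photos of the empty scene
#' (taken under different lighting) and stores their rounded coordinates with
#' the image colour at each point. Entries are deduplicated by rounded
#' coordinates.
#'
#' @param photos list of RGB arrays, all of the same dimensions.
#' @param params a [sift_params()] list.
#' @return A list of class `background_reference` with a tibble `entries`
#'   (`x`, `y`, `R`, `G`, `B`), the frame `dim`, and `source_count`.
#' @export
build_background_reference <- function(photos, params = sift_params()) {
  if (length(photos) < 1) stop_domain("need at least one reference photo")
  dims <- unique(lapply(photos, function(p) dim(p)[1:2]))
  if (length(dims) != 1) stop_domain("reference photos must share dimensions")
  entries <- purrr::map_dfr(photos, function(p) {
    kp <- detect_keypoints(p, params)
    if (nrow(kp) == 0) return(tibble(x = integer(), y = integer(),
                                     R = numeric(), G = numeric(), B = numeric()))
    x <- round_half_up(kp$x); y <- round_half_up(kp$y)
    tibble(x = x, y = y,
           R = p[cbind(y, x, 1)], G = p[cbind(y, x, 2)], B = p[cbind(y, x, 3)])
  })
  entries <- dplyr::distinct(entries, .data$x, .data$y, .keep_all = TRUE)
  structure(list(entries = entries, dim = dims[[1]],
                 source_count = length(photos)),
            class = "background_reference")
}

#' @rdname build_background_reference
#' @param ref a `background_reference`.
#' @param path JSON file path.
#' @export
write_background_reference <- function(ref, path) {
  jsonlite::write_json(list(entries = ref$entries, dim = ref$dim,
                            source_count = ref$source_count),
                       path, digits = NA)
  invisible(path)
}

#' @rdname build_background_reference
#' @export
read_background_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(entries = as_tibble(j$entries), dim = j$dim,
                 source_count = j$source_count),
            class = "background_reference")
}

#' Remove background key points
#'
#' Deletes every key point whose rounded position lies within `pos_tol`
#' pixels of a stored reference entry and whose image colour is within
#' `color_tol` per channel of the colour stored for that entry. Survivor
#' order is preserved.
#'
#' @param kps key-point tibble.
#' @param img the RGB image the key points came from.
#' @param ref a [build_background_reference()] result.
#' @param pos_tol positional tolerance in pixels.
#' @param color_tol per-channel colour tolerance.
#' @return The surviving rows of `kps`.
#' @export
filter_background <- function(kps, img, ref, pos_tol = 2, color_tol = 20) {
  if (nrow(kps) == 0 || nrow(ref$entries) == 0) return(kps)
  x <- round_half_up(kps$x); y <- round_half_up(kps$y)
  col <- cbind(img[cbind(y, x, 1)], img[cbind(y, x, 2)], img[cbind(y, x, 3)])
  e <- ref$entries
  drop <- vapply(seq_len(nrow(kps)), function(n) {
    near <- abs(e$x - x[n]) <= pos_tol & abs(e$y - y[n]) <= pos_tol
    if (!any(near)) return(FALSE)
    any(abs(e$R[near] - col[n, 1]) <= color_tol &
        abs(e$G[near] - col[n, 2]) <= color_tol &
        abs(e$B[near] - col[n, 3]) <= color_tol)
  }, logical(1))
  kps[!drop, ]
}

# median colour of the 3x3 neighbourhood (clamped at borders)
median_color <- function(img, x, y) {
  h <- dim(img)[1]; w <- dim(img)[2]
  ii <- pmin(pmax(y + rep(-1:1, 3), 1), h)
  jj <- pmin(pmax(x + rep(-1:1, each = 3), 1), w)
  vapply(1:3, function(c) stats::median(img[cbind(ii, jj, c)]), numeric(1))
}

#' Keep key points with skin-like colours
#'
#' Retains a key point iff the median colour of its 3 x 3 neighbourhood is
#' within the palette tolerance of at least one anchor.
#'
#' @inheritParams filter_background
#' @param palette a [skin_palette()].
#' @return The surviving rows of `kps`.
#' @export
filter_palette <- function(kps, img, palette = default_skin_palette()) {
  if (nrow(palette$colors) < 1) stop_domain("palette must be non-empty")
  if (nrow(kps) == 0) return(kps)
  x <- round_half_up(kps$x); y <- round_half_up(kps$y)
  keep <- vapply(seq_len(nrow(kps)), function(n) {
    mc <- median_color(img, x[n], y[n])
    any(apply(abs(sweep(palette$colors, 2, mc)), 1, max) <= palette$tolerance)
  }, logical(1))
  kps[keep, ]
}

#' Remove key points on long thin structures
#'
#' Grows the same-colour region around each key point (on the grayscale
#' image) and removes the key point when the region's bounding-box aspect
#' ratio exceeds `aspect_limit` — border lines and other elongated shapes
#' are not nevi.
#'
#' @inheritParams filter_background
#' @param aspect_limit maximum allowed bounding-box aspect ratio (> 1).
#' @param tol intensity tolerance for region growth.
#' @return The surviving rows of `kps`.
#' @export
filter_elongated <- function(kps, img, aspect_limit = 5, tol = 10) {
  if (aspect_limit <= 1) stop_domain("aspect_limit must be > 1")
  if (nrow(kps) == 0) return(kps)
  g <- to_gray(img)
  x <- round_half_up(kps$x); y <- round_half_up(kps$y)
  keep <- vapply(seq_len(nrow(kps)), function(n) {
    reg <- region_grow(g, x[n], y[n], tol)
    wd <- reg$bbox[3] - reg$bbox[1] + 1
    ht <- reg$bbox[4] - reg$bbox[2] + 1
    max(wd, ht) / min(wd, ht) <= aspect_limit
  }, logical(1))
  kps[keep, ]
}
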