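#' Synthetic nevus specification
#'
#' Parameterizes one rendered nevus by the clinical ABCD warning signs:
#' asymmetry (the two halves of the ellipse get different semi-axes), border
#' fuzziness (width of the edge gradient as a fraction of the radius),
#' colour variegation (`n_shades` concentric irregular shade zones) and
#' diameter in millimetres. The generator's labelling rule mirrors the
#' warning signs: the label is forced to `"suspicious"` when
#' `diameter_mm > 6`, `asymmetry > 0.5` or `n_shades >= 3`.
#'
#' @param center `c(x, y)` pixel centre.
#' @param diameter_mm diameter in millimetres (> 0).
#' @param px_per_mm pixel pitch; the default 10 maps the 6 mm diameter
#'   criterion to 60 px.
#' @param asymmetry in `[0, 1]`.
#' @param border_fuzz in `[0, 1]`.
#' @param n_shades integer >= 1.
#' @param base_color `c(R, G, B)` of the pigment.
#' @param rotation orientation of the ellipse, radians.
#' @param label optional; defaults to the rule above.
#' @return A list of class `nevus_spec`.
#' @export
nevus_spec <- function(center, diameter_mm, px_per_mm = 10, asymmetry = 0,
                       border_fuzz = 0.1, n_shades = 1L,
                       base_color = c(150, 105, 85), rotation = 0,
                       label = NULL) {
  stopifnot(diameter_mm > 0, px_per_mm > 0, asymmetry >= 0, asymmetry <= 1,
            border_fuzz >= 0, border_fuzz <= 1, n_shades >= 1)
  forced <- diameter_mm > 6 || asymmetry > 0.5 || n_shades >= 3
  if (is.null(label)) label <- if (forced) "suspicious" else "benign"
  if (forced && label != "suspicious")
    stop_domain("spec meets a warning criterion; label must be 'suspicious'")
  structure(list(center = center, diameter_mm = diameter_mm,
                 px_per_mm = px_per_mm, asymmetry = asymmetry,
                 border_fuzz = border_fuzz, n_shades = as.integer(n_shades),
                 base_color = base_color, rotation = rotation, label = label),
            class = "nevus_spec")
}

# low-frequency tone variation: coarse seeded grid upsampled bilinearly
smooth_field <- function(h, w, cells = 7, amplitude = 1) {
  g <- matrix(runif(cells * cells, -1, 1), cells, cells)
  amplitude * bilinear_plane(g, w, h)
}

skin_texture <- function(h, w, base = c(224, 172, 150), wave = 10, noise = 2.5) {
  field <- smooth_field(h, w, amplitude = wave)
  out <- array(0, dim = c(h, w, 3L))
  for (c in 1:3)
    out[, , c] <- clamp255(round_half_up(base[c] + field +
                                           rnorm(h * w, sd = noise)))
  out
}

wall_texture <- function(h, w, base = c(120, 135, 150), noise = 2) {
  field <- smooth_field(h, w, amplitude = 6)
  out <- array(0, dim = c(h, w, 3L))
  for (c in 1:3)
    out[, , c] <- clamp255(round_half_up(base[c] + field +
                                           rnorm(h * w, sd = noise)))
  out
}

# render one nevus onto img; returns list(img, mask)
render_nevus <- function(img, spec) {
  h <- dim(img)[1]; w <- dim(img)[2]
  r <- spec$diameter_mm * spec$px_per_mm / 2
  a <- spec$asymmetry; f <- max(spec$border_fuzz, 0.02)
  rx <- r
  ry_up <- r * (1 - a / 2 + a / 4)
  ry_dn <- r * (1 - a / 2 - a / 4)
  rmax <- ceiling(max(rx, ry_up, ry_dn) * (1 + f) + 2)
  cx <- spec$center[1]; cy <- spec$center[2]
  xs <- max(1, floor(cx - rmax)):min(w, ceiling(cx + rmax))
  ys <- max(1, floor(cy - rmax)):min(h, ceiling(cy + rmax))
  dx <- matrix(xs - cx, length(ys), length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, length(ys), length(xs))
  th <- spec$rotation
  du <- dx * cos(th) + dy * sin(th)
  dv <- -dx * sin(th) + dy * cos(th)
  ry <- ifelse(dv < 0, ry_up, ry_dn)
  rho <- sqrt((du / rx)^2 + (dv / ry)^2)
  alpha <- pmin(pmax((1 + f / 2 - rho) / f, 0), 1)
  ns <- spec$n_shades
  if (ns > 1) {
    ang <- atan2(dv, du)
    wob <- 1 + 0.15 * sin(3 * ang + spec$rotation * 5) *
      (ns >= 3)               # irregular zone borders only when variegated
    zone <- pmin(floor(pmax(rho * wob, 0) * ns) + 1, ns)
    mult <- seq(0.7, 1.2, length.out = ns)[zone]
  } else mult <- 1
  mask <- matrix(FALSE, h, w)
  mask[ys, xs] <- alpha > 0.5
  for (c in 1:3) {
    patch <- img[ys, xs, c]
    col <- pmin(pmax(spec$base_color[c] * mult, 0), 255)
    img[ys, xs, c] <- round_half_up(alpha * col + (1 - alpha) * patch)
  }
  list(img = img, mask = mask)
}

random_nevus_spec <- function(center, class, px_per_mm) {
  if (class == "suspicious") {
    nevus_spec(center,
               diameter_mm = runif(1, 6.2, 7.2), px_per_mm = px_per_mm,
               asymmetry = runif(1, 0.55, 0.8),
               border_fuzz = runif(1, 0.4, 0.8),
               n_shades = sample(3:4, 1),
               base_color = c(95, 62, 48) + round(runif(3, -8, 8)),
               rotation = runif(1, 0, pi))
  } else {
    nevus_spec(center,
               diameter_mm = runif(1, 2, 4), px_per_mm = px_per_mm,
               asymmetry = runif(1, 0, 0.3),
               border_fuzz = runif(1, 0.05, 0.25),
               n_shades = 1L,
               base_color = c(150, 105, 85) + round(runif(3, -10, 10)),
               rotation = runif(1, 0, pi))
  }
}

clutter_palette <- function() rbind(
  c(30, 40, 120), c(40, 130, 60), c(245, 245, 245), c(10, 10, 10),
  c(200, 200, 60)
)

#' Render a synthetic body scene with ground truth
#'
#' Emulates a photo taken in front of a mirror: a skin-textured region (low
#' frequency tone variation plus Gaussian noise) covering at least half the
#' frame, a wall-textured remainder with rectangular clutter objects, and
#' `n_nevi` nevi rendered from seeded [nevus_spec()]s. Fully determined by
#' the seed.
#'
#' @param w,h frame size in pixels (>= 128). The default matches a typical
#'   800 x 600 indoor camera frame.
#' @param n_nevi number of nevi to place on the skin.
#' @param clutter number of clutter rectangles on the wall.
#' @param seed RNG seed.
#' @param nevus_class `"random"`, `"benign"` or `"suspicious"`; class of the
#'   placed nevi.
#' @param px_per_mm pixel pitch used for all nevi.
#' @return A list of class `scene_truth`: `image`, `nevi` (list of specs,
#'   each with its logical pixel `mask`), `background_objects` (tibble of
#'   bounding boxes), `skin_mask`, `background_image` (the same frame with
#'   the skin region replaced by wall), and the generating parameters.
#' @export
make_scene <- function(w = 800, h = 600, n_nevi = 1, clutter = 3, seed = 0,
                       nevus_class = "random", px_per_mm = 10) {
  if (w < 128 || h < 128) stop_domain("scene must be at least 128 x 128")
  set.seed(seed)
  wall <- wall_texture(h, w)
  objects <- tibble(xmin = integer(), ymin = integer(),
                    xmax = integer(), ymax = integer())
  skin_w <- ceiling(0.55 * w)
  for (q in seq_len(clutter)) {
    ow <- sample(20:max(21, round(0.15 * w)), 1)
    oh <- sample(20:max(21, round(0.2 * h)), 1)
    ox <- sample(seq(skin_w + 1, max(skin_w + 2, w - ow)), 1)
    oy <- sample(seq(1, max(2, h - oh)), 1)
    col <- clutter_palette()[sample(nrow(clutter_palette()), 1), ]
    for (c in 1:3)
      wall[oy:(oy + oh - 1), ox:(ox + ow - 1), c] <-
        clamp255(round_half_up(col[c] + rnorm(oh * ow, sd = 2)))
    objects <- dplyr::bind_rows(objects, tibble(
      xmin = ox, ymin = oy, xmax = ox + ow - 1, ymax = oy + oh - 1))
  }
  img <- wall
  skin <- skin_texture(h, skin_w)
  img[, seq_len(skin_w), ] <- skin
  skin_mask <- matrix(FALSE, h, w)
  skin_mask[, seq_len(skin_w)] <- TRUE
  nevi <- list()
  occupied <- matrix(FALSE, h, w)
  for (q in seq_len(n_nevi)) {
    cls <- if (nevus_class == "random")
      sample(c("benign", "suspicious"), 1) else nevus_class
    placed <- FALSE
    for (try in 1:200) {
      spec <- random_nevus_spec(center = c(0, 0), class = cls,
                                px_per_mm = px_per_mm)
      r <- spec$diameter_mm * px_per_mm / 2
      margin <- ceiling(r * 2 + 4)
      if (skin_w - 2 * margin < 2 || h - 2 * margin < 2) next
      cx <- sample(seq(margin, skin_w - margin), 1)
      cy <- sample(seq(margin, h - margin), 1)
      box <- occupied[max(1, cy - margin):min(h, cy + margin),
                      max(1, cx - margin):min(w, cx + margin)]
      if (any(box)) next
      spec$center <- c(cx, cy)
      rn <- render_nevus(img, spec)
      img <- rn$img
      spec$mask <- rn$mask
      occupied <- occupied | rn$mask
      nevi[[length(nevi) + 1]] <- spec
      placed <- TRUE
      break
    }
    if (!placed) stop_domain("could not place the requested nevi disjointly")
  }
  structure(list(image = img, nevi = nevi, background_objects = objects,
                 skin_mask = skin_mask, background_image = wall,
                 w = w, h = h, seed = seed, px_per_mm = px_per_mm),
            class = "scene_truth")
}

#' Reference photos of the empty scene
#'
#' Re-renders the scene background (skin regions replaced by wall texture)
#' `n` times with a global brightness jitter, emulating the "several photos
#' under different lighting" used to build the background key-point
#' reference.
#'
#' @param scene a [make_scene()] result.
#' @param n number of photos (>= 1).
#' @param lighting_jitter maximum absolute global brightness offset
#'   (0-255 scale); 0 gives identical photos.
#' @param seed RNG seed for the offsets.
#' @return List of RGB arrays.
#' @export
make_background_photos <- function(scene, n = 3, lighting_jitter = 5,
                                   seed = 0) {
  if (n < 1) stop_domain("need n >= 1")
  set.seed(seed)
  offs <- round(runif(n, -lighting_jitter, lighting_jitter))
  lapply(offs, function(o) clamp255(scene$background_image + o))
}

render_cluster_patch <- function(target_dim, class,
                                 params = cluster_params()) {
  w <- target_dim[1]; h <- target_dim[2]
  img <- skin_texture(h, w)
  fill <- if (class == "suspicious") runif(1, 0.75, 0.95) else runif(1, 0.5, 0.7)
  diam_px <- fill * min(w, h)
  diameter_mm <- if (class == "suspicious") runif(1, 6.5, 9) else runif(1, 2.5, 4)
  base <- random_nevus_spec(c(0, 0), class, px_per_mm = 1)
  spec <- nevus_spec(center = c((w + 1) / 2 + runif(1, -2, 2),
                                (h + 1) / 2 + runif(1, -2, 2)),
                     diameter_mm = diameter_mm,
                     px_per_mm = diam_px / diameter_mm,
                     asymmetry = base$asymmetry,
                     border_fuzz = base$border_fuzz,
                     n_shades = base$n_shades,
                     base_color = base$base_color,
                     rotation = base$rotation)
  rn <- render_nevus(img, spec)
  # normalize exactly the way the live clusterer does, so the dataset has the
  # same appearance statistics as pipeline-extracted clusters: flatten, grow
  # the same-colour region from the centre, crop to its bounding box, restore
  # original colours, resize back to the uniform cluster size
  proc <- adjust_contrast(gamma_correct(to_gray(rn$img), params$gamma),
                          params$omega)
  reg <- region_grow(proc, round_half_up(spec$center[1]),
                     round_half_up(spec$center[2]), params$color_tol)
  bb <- if (reg$size >= params$min_region && reg$size < 0.9 * w * h) reg$bbox
  else {  # degenerate growth: fall back to the rendered mask's box
    px <- which(rn$mask, arr.ind = TRUE)
    c(min(px[, 2]), min(px[, 1]), max(px[, 2]), max(px[, 1]))
  }
  crop <- rn$img[bb[2]:bb[4], bb[1]:bb[3], , drop = FALSE]
  out <- resize_image(crop, w, h)
  structure(list(image = out, label = class, spec = spec, mask = rn$mask,
                 region_size = reg$size, state = "raw"),
            class = "dermo_cluster")
}

#' Labelled synthetic cluster dataset
#'
#' Renders balanced benign and suspicious nevus clusters at the final
#' cluster size, emulating the class structure of a dermoscopy archive:
#' benign clusters are near-round, single-shade, sharply bordered and
#' lighter; suspicious clusters are asymmetric, fuzzy-bordered, multi-shade,
#' darker and relatively larger. Deterministic for a fixed seed.
#'
#' @param n_per_class clusters per label (>= 1).
#' @param target_dim `c(width, height)` of each cluster image.
#' @param seed RNG seed.
#' @return List of `2 * n_per_class` labelled `dermo_cluster` objects
#'   (fields `image`, `label`, `spec`, `mask`).
#' @export
make_cluster_dataset <- function(n_per_class = 50, target_dim = c(64L, 64L),
                                 seed = 0) {
  if (n_per_class < 1) stop_domain("need n_per_class >= 1")
  set.seed(seed)
  out <- vector("list", 2 * n_per_class)
  for (q in seq_len(n_per_class)) {
    out[[2 * q - 1]] <- render_cluster_patch(target_dim, "benign")
    out[[2 * q]] <- render_cluster_patch(target_dim, "suspicious")
  }
  out
}

#' Plain-skin exemplar patches
#'
#' Nevus-free skin textures at cluster size, used as the `"skin"` side of
#' the screening exemplar database.
#'
#' @inheritParams make_cluster_dataset
#' @param n number of patches.
#' @return List of RGB arrays.
#' @export
make_skin_patches <- function(n = 20, target_dim = c(64L, 64L), seed = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(q) skin_texture(target_dim[2], target_dim[1]))
}

#' Write a cluster dataset to disk
#'
#' Saves each cluster as PNG plus a manifest CSV (`path`, `label`, and the
#' generating spec fields).
#'
#' @param clusters list from [make_cluster_dataset()].
#' @param dir output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cluster_dataset <- function(clusters, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::imap_dfr(clusters, function(cl, q) {
    fn <- file.path(dir, sprintf("cluster_%03d.png", q))
    save_image(cl$image, fn)
    sp <- cl$spec
    tibble(path = fn, label = cl$label,
           diameter_mm = sp$diameter_mm, asymmetry = sp$asymmetry,
           border_fuzz = sp$border_fuzz, n_shades = sp$n_shades)
  })
  utils::write.csv(rows, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(rows)
}
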