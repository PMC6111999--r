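#' Detector parameters
#'
#' Parameters of the scale-space key-point detector. `sigma0` is the base
#' blur scale of the pyramid, `k` the multiplicative scale step between
#' adjacent levels, `levels_per_octave` the number of scale intervals per
#' octave, `contrast_threshold` the minimum interpolated difference-of-
#' Gaussians magnitude (on intensities normalized to `[0, 1]`), and `r` the
#' edge-rejection ratio: a candidate is discarded when the spatial Hessian
#' satisfies `tr(H)^2 / det(H) >= (r + 1)^2 / r` (or `det(H) <= 0`).
#'
#' @param sigma0 base scale (> 0).
#' @param k scale multiplier per level (> 1).
#' @param levels_per_octave scale intervals per octave (>= 3).
#' @param octaves number of octaves (>= 1); each halves the image.
#' @param contrast_threshold low-contrast rejection threshold (>= 0).
#' @param r edge-ratio parameter (> 1).
#' @param orientation_bins bins of the orientation histogram (>= 1).
#' @return A list of class `sift_params`.
#' @export
sift_params <- function(sigma0 = 1.6, k = 2^(1 / 3), levels_per_octave = 3L,
                        octaves = 4L, contrast_threshold = 0.03, r = 10,
                        orientation_bins = 36L) {
  stopifnot(sigma0 > 0, k > 1, levels_per_octave >= 3, octaves >= 1,
            contrast_threshold >= 0, r > 1, orientation_bins >= 1)
  structure(list(sigma0 = sigma0, k = k,
                 levels_per_octave = as.integer(levels_per_octave),
                 octaves = as.integer(octaves),
                 contrast_threshold = contrast_threshold, r = r,
                 orientation_bins = as.integer(orientation_bins)),
            class = "sift_params")
}

gaussian_1d <- function(sigma, radius) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Discrete 2-D Gaussian kernel
#'
#' Samples `G(x, y) = exp(-(x^2 + y^2) / (2 sigma^2)) / (2 pi sigma^2)` on the
#' integer grid `[-radius, radius]^2` and renormalizes the samples to sum 1.
#'
#' @param sigma standard deviation (> 0).
#' @param radius half-width of the kernel (>= 1).
#' @return A `(2 radius + 1)` square matrix summing to 1.
#' @export
gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  if (!is.numeric(sigma) || sigma <= 0) stop_domain("sigma must be > 0")
  x <- (-radius):radius
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2)) / (2 * pi * sigma^2)
  g / sum(g)
}

#' Dense 2-D filtering
#'
#' Correlates the image with a kernel of odd side lengths; borders are handled
#' by edge replication. Returns an unclamped real-valued plane.
#'
#' @param img numeric matrix.
#' @param kernel numeric matrix with odd dimensions.
#' @return Numeric matrix of the same size as `img`.
#' @export
convolve_image <- function(img, kernel) {
  if (!is.matrix(kernel) || nrow(kernel) %% 2 == 0 || ncol(kernel) %% 2 == 0)
    stop_domain("kernel must be a matrix with odd side lengths")
  conv2d_replicate_cpp(img, kernel)
}

gaussian_blur <- function(plane, sigma) {
  if (sigma <= 1e-8) return(plane)
  sep_filter_replicate_cpp(plane, gaussian_1d(sigma, max(1L, ceiling(3 * sigma))))
}

#' Build the Gaussian / difference-of-Gaussians pyramid
#'
#' Intensities are first normalized by the image maximum (so uniformly
#' rescaling all intensities does not change the pyramid up to that factor,
#' and the contrast threshold acts on a per-image normalized scale). Each
#' octave holds `levels_per_octave + 3` Gaussian planes at scales
#' `sigma0 * k^(l-1)` and `levels_per_octave + 2` DoG planes formed by
#' pixelwise subtraction of adjacent Gaussians; the next octave starts from
#' the plane at twice the base scale, downsampled by 2.
#'
#' @param img gray matrix (or RGB array, converted) of at least 16 x 16 after
#'   the last requested octave's downsampling.
#' @param params a [sift_params()] list.
#' @return A list of class `scale_space` with elements `gaussians` and `dogs`
#'   (lists of per-octave lists of matrices), `sigmas` (octave-relative
#'   scales), and `dim` (base image size).
#' @export
build_scale_space <- function(img, params = sift_params()) {
  if (!is.matrix(img)) img <- to_gray(as_rgb_image(img))
  h <- nrow(img); w <- ncol(img)
  if (min(h, w) < 16) stop_domain("image must be at least 16 x 16")
  if (min(h, w) / 2^(params$octaves - 1) < 16)
    stop_domain("image too small for the requested number of octaves")
  mx <- max(img)
  base <- if (mx > 0) img / mx else img * 0
  s <- params$levels_per_octave
  n_gauss <- s + 3L
  sig <- params$sigma0 * params$k^(0:(n_gauss - 1L))
  gaussians <- vector("list", params$octaves)
  dogs <- vector("list", params$octaves)
  oct_base <- gaussian_blur(base, params$sigma0)
  for (o in seq_len(params$octaves)) {
    g <- vector("list", n_gauss)
    g[[1]] <- oct_base
    for (l in 2:n_gauss)
      g[[l]] <- gaussian_blur(g[[l - 1]], sqrt(sig[l]^2 - sig[l - 1]^2))
    gaussians[[o]] <- g
    dogs[[o]] <- lapply(seq_len(n_gauss - 1L), function(l) g[[l + 1]] - g[[l]])
    if (o < params$octaves) {
      # plane at 2*sigma0 relative scale becomes the next octave's base
      nxt <- g[[s + 1L]]
      oct_base <- nxt[seq(1, nrow(nxt), by = 2), seq(1, ncol(nxt), by = 2), drop = FALSE]
    }
  }
  structure(list(gaussians = gaussians, dogs = dogs, sigmas = sig,
                 params = params, dim = c(h, w)),
            class = "scale_space")
}

#' Candidate extrema of the DoG stack
#'
#' A pixel is a candidate iff its DoG value is strictly greater than all, or
#' strictly less than all, of its 26 neighbours: the 8 in its own 3 x 3
#' square plus 9 + 9 in the two adjacent DoG levels.
#'
#' @param ss a [build_scale_space()] result.
#' @return Tibble with columns `octave`, `i` (row), `j` (column), `level` and
#'   `value` (DoG value), all in octave coordinates.
#' @export
detect_extrema <- function(ss) {
  stopifnot(inherits(ss, "scale_space"))
  out <- purrr::map_dfr(seq_along(ss$dogs), function(o) {
    dg <- ss$dogs[[o]]
    if (length(dg) < 3L) stop_domain("need at least 3 DoG levels per octave")
    cube <- array(unlist(dg, use.names = FALSE),
                  dim = c(nrow(dg[[1]]), ncol(dg[[1]]), length(dg)))
    ex <- find_extrema_cpp(as.numeric(cube), dim(cube))
    if (nrow(ex) == 0) return(tibble(octave = integer(), i = integer(),
                                     j = integer(), level = integer(),
                                     value = numeric()))
    tibble(octave = o, i = ex[, 1], j = ex[, 2], level = ex[, 3],
           value = cube[ex])
  })
  out
}

# 3-D gradient / Hessian of the DoG stack at integer (i, j, l), central diffs
dog_derivs <- function(cube, i, j, l) {
  g <- c(
    0.5 * (cube[i, j + 1, l] - cube[i, j - 1, l]),   # d/dx
    0.5 * (cube[i + 1, j, l] - cube[i - 1, j, l]),   # d/dy
    0.5 * (cube[i, j, l + 1] - cube[i, j, l - 1])    # d/dsigma
  )
  v <- cube[i, j, l]
  dxx <- cube[i, j + 1, l] + cube[i, j - 1, l] - 2 * v
  dyy <- cube[i + 1, j, l] + cube[i - 1, j, l] - 2 * v
  dss <- cube[i, j, l + 1] + cube[i, j, l - 1] - 2 * v
  dxy <- 0.25 * (cube[i + 1, j + 1, l] - cube[i + 1, j - 1, l] -
                 cube[i - 1, j + 1, l] + cube[i - 1, j - 1, l])
  dxs <- 0.25 * (cube[i, j + 1, l + 1] - cube[i, j - 1, l + 1] -
                 cube[i, j + 1, l - 1] + cube[i, j - 1, l - 1])
  dys <- 0.25 * (cube[i + 1, j, l + 1] - cube[i - 1, j, l + 1] -
                 cube[i + 1, j, l - 1] + cube[i - 1, j, l - 1])
  list(g = g, H = matrix(c(dxx, dxy, dxs, dxy, dyy, dys, dxs, dys, dss), 3, 3),
       H2 = matrix(c(dxx, dxy, dxy, dyy), 2, 2), value = v)
}

#' Sub-pixel localization with contrast and edge rejection
#'
#' Each candidate is refined by a quadratic (Taylor) fit of the DoG stack:
#' the offset solves the stationary condition of the local expansion via the
#' 3-D Hessian; the candidate is re-anchored to the neighbouring pixel when
#' any offset component exceeds 0.5 (at most 5 retries). Refined points are
#' rejected when the interpolated magnitude `|D(x)|` falls below
#' `contrast_threshold`, and when the 2 x 2 spatial Hessian indicates an
#' edge (`det(H) <= 0` or `tr(H)^2 / det(H) >= (r + 1)^2 / r`).
#'
#' @param candidates tibble from [detect_extrema()].
#' @param ss the same `scale_space`.
#' @param params a [sift_params()] list.
#' @return Tibble of surviving key points: base-image `x`, `y` (sub-pixel),
#'   `sigma`, `response`, plus octave-coordinate bookkeeping columns
#'   (`octave`, `level`, `oi`, `oj`). The attribute `rejections` counts
#'   `low_contrast`, `edge` and `unstable` (singular/out-of-range) discards.
#' @export
localize_and_filter <- function(candidates, ss, params = ss$params) {
  stopifnot(inherits(ss, "scale_space"))
  edge_thr <- (params$r + 1)^2 / params$r
  rej <- c(low_contrast = 0L, edge = 0L, unstable = 0L)
  rows <- vector("list", nrow(candidates))
  cubes <- lapply(ss$dogs, function(dg)
    array(unlist(dg, use.names = FALSE),
          dim = c(nrow(dg[[1]]), ncol(dg[[1]]), length(dg))))
  for (n in seq_len(nrow(candidates))) {
    o <- candidates$octave[n]
    cube <- cubes[[o]]
    i <- candidates$i[n]; j <- candidates$j[n]; l <- candidates$level[n]
    hh <- dim(cube)[1]; ww <- dim(cube)[2]; LL <- dim(cube)[3]
    ok <- FALSE
    for (try in 1:6) {
      if (i < 2 || j < 2 || l < 2 || i > hh - 1 || j > ww - 1 || l > LL - 1) break
      d <- dog_derivs(cube, i, j, l)
      off <- tryCatch(solve(d$H, -d$g), error = function(e) NULL)
      if (is.null(off) || any(!is.finite(off))) break
      if (all(abs(off) <= 0.5) || try == 6) { ok <- TRUE; break }
      j <- j + sign(off[1]) * (abs(off[1]) > 0.5)
      i <- i + sign(off[2]) * (abs(off[2]) > 0.5)
      l <- l + sign(off[3]) * (abs(off[3]) > 0.5)
    }
    if (!ok) { rej["unstable"] <- rej["unstable"] + 1L; next }
    val <- d$value + 0.5 * sum(d$g * off)
    if (abs(val) < params$contrast_threshold) {
      rej["low_contrast"] <- rej["low_contrast"] + 1L; next
    }
    detH <- det(d$H2); trH <- sum(diag(d$H2))
    if (detH <= 0 || trH^2 / detH >= edge_thr) {
      rej["edge"] <- rej["edge"] + 1L; next
    }
    scale_mult <- 2^(o - 1)
    rows[[n]] <- tibble(
      x = ((j - 1) + off[1]) * scale_mult + 1,
      y = ((i - 1) + off[2]) * scale_mult + 1,
      sigma = params$sigma0 * params$k^((l - 1) + off[3]) * scale_mult,
      response = val, octave = o, level = l, oi = i, oj = j
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- dplyr::filter(out, .data$x >= 1, .data$x <= ss$dim[2],
                         .data$y >= 1, .data$y <= ss$dim[1])
  } else {
    out <- tibble(x = numeric(), y = numeric(), sigma = numeric(),
                  response = numeric(), octave = integer(), level = integer(),
                  oi = integer(), oj = integer())
  }
  attr(out, "rejections") <- rej
  out
}

# gradient magnitude / orientation at integer pixels of a Gaussian plane,
# finite differences without the 1/2 factor:
# m = sqrt((L(x+1,y)-L(x-1,y))^2 + (L(x,y+1)-L(x,y-1))^2)
grad_at <- function(plane, i, j) {
  dx <- plane[cbind(i, j + 1)] - plane[cbind(i, j - 1)]
  dy <- plane[cbind(i + 1, j)] - plane[cbind(i - 1, j)]
  list(m = sqrt(dx^2 + dy^2), phi = atan2(dy, dx))
}

#' Orientation assignment
#'
#' For each localized key point, gradient magnitude and orientation are
#' computed on the Gaussian plane nearest the key point's scale; a histogram
#' over the 3 x 3 neighbourhood, weighted by magnitude times a Gaussian of
#' the pixel distance at the key point's octave-relative scale, is
#' accumulated, and one key point is emitted per histogram peak reaching 80%
#' of the maximum bin. Key points too close to the plane border are dropped.
#'
#' @param kps tibble from [localize_and_filter()].
#' @param ss the same `scale_space`.
#' @param params a [sift_params()] list.
#' @return Tibble like `kps` with an added `orientation` column (radians in
#'   `[0, 2 pi)`); possibly more than one row per input key point.
#' @export
assign_orientation <- function(kps, ss, params = ss$params) {
  nb <- params$orientation_bins
  out <- vector("list", nrow(kps))
  for (n in seq_len(nrow(kps))) {
    o <- kps$octave[n]; l <- kps$level[n]
    plane <- ss$gaussians[[o]][[l]]
    i <- kps$oi[n]; j <- kps$oj[n]
    if (i < 3 || j < 3 || i > nrow(plane) - 2 || j > ncol(plane) - 2) next
    nbh <- expand.grid(di = -1:1, dj = -1:1)
    g <- grad_at(plane, i + nbh$di, j + nbh$dj)
    sig <- params$sigma0 * params$k^(l - 1)
    wt <- g$m * exp(-(nbh$di^2 + nbh$dj^2) / (2 * sig^2)) / (2 * pi * sig^2)
    if (sum(wt) <= 0) next
    phi <- g$phi %% (2 * pi)
    bin <- pmin(floor(phi / (2 * pi) * nb), nb - 1) + 1
    hist <- numeric(nb)
    for (q in seq_along(bin)) hist[bin[q]] <- hist[bin[q]] + wt[q]
    mx <- max(hist)
    if (mx <= 0) next
    left <- hist[c(nb, 1:(nb - 1))]; right <- hist[c(2:nb, 1)]
    peaks <- which(hist >= 0.8 * mx & hist >= left & hist >= right)
    # collapse plateaus of equal neighbouring bins to their first bin
    if (length(peaks) > 1)
      peaks <- peaks[c(TRUE, !(diff(peaks) == 1 &
                               hist[peaks[-length(peaks)]] == hist[peaks[-1]]))]
    for (p in peaks) {
      row <- kps[n, ]
      row$orientation <- (p - 0.5) * 2 * pi / nb
      out[[n]] <- dplyr::bind_rows(out[[n]], row)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0)
    res <- dplyr::mutate(kps[0, ], orientation = numeric())
  res
}

#' Local descriptor
#'
#' Samples a 16 x 16 grid around the key point, rotated to its orientation,
#' on the key point's Gaussian plane; the grid is divided into 4 x 4 even
#' areas and an 8-bin histogram of gradient magnitudes (orientations taken
#' relative to the key point's) is accumulated per area, giving a 128-vector
#' which is L2-normalized (a zero vector stays zero). Key points whose
#' neighbourhood exceeds the plane are dropped.
#'
#' @param kps tibble from [assign_orientation()].
#' @param ss the same `scale_space`.
#' @return `kps` with a `descriptor` list-column of 128-vectors; rows whose
#'   neighbourhood left the image are removed.
#' @export
compute_descriptor <- function(kps, ss) {
  grid <- expand.grid(u = seq(-7.5, 7.5, by = 1), v = seq(-7.5, 7.5, by = 1))
  cell <- (ceiling((grid$u + 8) / 4) - 1) * 4 + ceiling((grid$v + 8) / 4)
  keep <- logical(nrow(kps))
  desc <- vector("list", nrow(kps))
  for (n in seq_len(nrow(kps))) {
    o <- kps$octave[n]; l <- kps$level[n]
    plane <- ss$gaussians[[o]][[l]]
    th <- kps$orientation[n]
    rx <- kps$oj[n] + round(grid$u * cos(th) - grid$v * sin(th))
    ry <- kps$oi[n] + round(grid$u * sin(th) + grid$v * cos(th))
    if (min(rx, ry) < 2 || max(rx) > ncol(plane) - 1 || max(ry) > nrow(plane) - 1)
      next
    g <- grad_at(plane, ry, rx)
    rel <- (g$phi - th) %% (2 * pi)
    ob <- pmin(floor(rel / (2 * pi) * 8), 7) + 1
    d <- numeric(128)
    idx <- (cell - 1) * 8 + ob
    for (q in seq_along(idx)) d[idx[q]] <- d[idx[q]] + g$m[q]
    nrm <- sqrt(sum(d^2))
    if (nrm > 0) d <- d / nrm
    desc[[n]] <- d
    keep[n] <- TRUE
  }
  out <- kps[keep, ]
  out$descriptor <- desc[keep]
  out
}

#' Detect key points in an image
#'
#' Full detector: pyramid construction, 26-neighbour extremum scan, Taylor
#' localization with contrast and edge rejection, orientation assignment and
#' descriptor extraction.
#'
#' @param img gray matrix or RGB array.
#' @param params a [sift_params()] list.
#' @return Tibble with one row per oriented key point: `x`, `y`, `sigma`,
#'   `orientation`, `response`, `octave`, `level` and a `descriptor`
#'   list-column.
#' @export
detect_keypoints <- function(img, params = sift_params()) {
  ss <- build_scale_space(img, params)
  kps <- detect_extrema(ss)
  kps <- localize_and_filter(kps, ss, params)
  kps <- assign_orientation(kps, ss, params)
  kps <- compute_descriptor(kps, ss)
  kps
}

#' Write key points to CSV
#'
#' Debug dump of the positional columns (descriptors omitted).
#'
#' @param kps key-point tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(kps, path) {
  utils::write.csv(
    dplyr::select(kps, dplyr::any_of(c("x", "y", "sigma", "orientation", "response"))),
    path, row.names = FALSE)
  invisible(path)
}
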