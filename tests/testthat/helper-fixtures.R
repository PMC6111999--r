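# Fixtures are generated in code; oracles here are deliberately naive
# (quadruple loops, breadth-first search, exhaustive scans) and independent
# of the package's implementation paths.

rand_rgb <- function(h, w, seed = 1) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3L))
}

rand_gray <- function(h, w, seed = 1, levels = 0:255) {
  set.seed(seed)
  matrix(sample(levels, h * w, replace = TRUE), h, w)
}

# isotropic Gaussian blob image. The default centre is slightly off the pixel
# grid's symmetry axes: a perfectly centred blob produces exact value ties
# among the four central pixels and a strict extremum test then (correctly)
# finds nothing. `ramp` adds a linear intensity gradient along +x; a linear
# term vanishes in every difference of Gaussians, so it leaves the extremum
# untouched while giving the key point a well-defined orientation.
blob_image <- function(n = 64, cx = 0.47 * n, cy = 0.52 * n,
                       sigma = 5, amplitude = 255, aspect = 1, ramp = 0) {
  xs <- matrix(rep(seq_len(n), each = n), n)
  ys <- matrix(rep(seq_len(n), n), n)
  b <- exp(-((xs - cx)^2 / (aspect^2) + (ys - cy)^2) / (2 * sigma^2))
  img <- amplitude * b + ramp * (xs - 1)
  pmax(pmin(img, amplitude + ramp * (n - 1)), 0)
}

step_edge_image <- function(n = 64) {
  img <- matrix(0, n, n)
  img[, (n %/% 2 + 1):n] <- 255
  img
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

# --- independent oracles -------------------------------------------------

# dense 2-D correlation with edge replication, quadruple loop
oracle_conv_replicate <- function(img, ker) {
  h <- nrow(img); w <- ncol(img)
  ri <- nrow(ker) %/% 2; rj <- ncol(ker) %/% 2
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    acc <- 0
    for (a in seq_len(nrow(ker))) for (b in seq_len(ncol(ker))) {
      ii <- min(max(i + a - ri - 1, 1), h)
      jj <- min(max(j + b - rj - 1, 1), w)
      acc <- acc + img[ii, jj] * ker[a, b]
    }
    out[i, j] <- acc
  }
  out
}

# valid-region multi-channel convolution with stride, direct summation
oracle_conv_valid <- function(x, wts, stride = 1) {
  h <- dim(x)[1]; w <- dim(x)[2]; C <- dim(x)[3]
  m <- dim(wts)[1]; F <- dim(wts)[4]
  oh <- (h - m) %/% stride + 1; ow <- (w - m) %/% stride + 1
  out <- array(0, dim = c(oh, ow, F))
  for (f in seq_len(F)) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    acc <- 0
    for (c in seq_len(C)) for (a in seq_len(m)) for (b in seq_len(m))
      acc <- acc + x[(i - 1) * stride + a, (j - 1) * stride + b, c] *
        wts[a, b, c, f]
    out[i, j, f] <- acc
  }
  out
}

# breadth-first flood fill over 4-neighbours, tolerance from the seed value
oracle_region_bfs <- function(img, sx, sy, tol) {
  h <- nrow(img); w <- ncol(img)
  ref <- img[sy, sx]
  mask <- matrix(FALSE, h, w)
  queue <- list(c(sy, sx))
  mask[sy, sx] <- TRUE
  while (length(queue) > 0) {
    p <- queue[[1]]; queue <- queue[-1]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ni <- p[1] + d[1]; nj <- p[2] + d[2]
      if (ni < 1 || nj < 1 || ni > h || nj > w || mask[ni, nj]) next
      if (abs(img[ni, nj] - ref) <= tol) {
        mask[ni, nj] <- TRUE
        queue[[length(queue) + 1]] <- c(ni, nj)
      }
    }
  }
  mask
}

# exhaustive strict 26-neighbourhood extremum scan of a DoG cube
oracle_extrema <- function(cube) {
  h <- dim(cube)[1]; w <- dim(cube)[2]; L <- dim(cube)[3]
  res <- NULL
  for (l in 2:(L - 1)) for (j in 2:(w - 1)) for (i in 2:(h - 1)) {
    v <- cube[i, j, l]
    nb <- cube[(i - 1):(i + 1), (j - 1):(j + 1), (l - 1):(l + 1)]
    others <- nb[-14]  # centre of the 3x3x3 block
    if (all(v > others) || all(v < others))
      res <- rbind(res, c(i, j, l))
  }
  res
}

# a handcrafted scale-space-like object exposing one Gaussian plane, enough
# for orientation/descriptor unit tests
fake_ss <- function(plane, params = sift_params()) {
  list(gaussians = list(list(plane)), dogs = list(), sigmas = params$sigma0,
       params = params, dim = dim(plane))
}

kp_row <- function(oi, oj, octave = 1L, level = 1L, orientation = 0) {
  tibble::tibble(x = oj, y = oi, sigma = 1.6, response = 1,
                 octave = octave, level = level, oi = oi, oj = oj,
                 orientation = orientation)
}

circular_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}
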