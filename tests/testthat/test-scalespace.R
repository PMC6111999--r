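test_that("Gaussian kernel is symmetric, normalized, and samples the density", {
  k <- gaussian_kernel(1.3, radius = 3)
  expect_equal(sum(k), 1)
  expect_equal(k, t(k))                       # reflection
  expect_equal(k, k[7:1, 7:1])                # 180 degree rotation
  expect_equal(k, t(k[7:1, ]))                # 90 degree rotation
  # proportional to exp(-(x^2+y^2)/(2 sigma^2)) at every sample
  x <- -3:3
  raw <- exp(-outer(x^2, x^2, "+") / (2 * 1.3^2)) / (2 * pi * 1.3^2)
  expect_equal(k, raw / sum(raw))
  expect_error(gaussian_kernel(0), class = "dermoscan_domain_error")
})

test_that("dense filtering matches the quadruple-loop oracle", {
  expect_equal(convolve_image(matrix(1:20, 4, 5), matrix(1, 1, 1)),
               matrix(1:20, 4, 5) * 1)
  const <- matrix(42, 6, 6)
  expect_equal(convolve_image(const, blur_kernel()), const)
  img <- rand_gray(5, 5, seed = 21)
  ker <- matrix(runif(9, -1, 1), 3, 3)
  expect_equal(convolve_image(img, ker), oracle_conv_replicate(img, ker))
  expect_error(convolve_image(img, matrix(1, 2, 2)),
               class = "dermoscan_domain_error")
})

test_that("scale space satisfies its definitional identities", {
  p <- sift_params(octaves = 2)
  ss <- build_scale_space(matrix(120, 48, 48), p)
  for (o in seq_along(ss$dogs))
    for (l in seq_along(ss$dogs[[o]])) {
      expect_true(all(abs(ss$dogs[[o]][[l]]) < 1e-12))
      expect_equal(ss$dogs[[o]][[l]] + ss$gaussians[[o]][[l]],
                   ss$gaussians[[o]][[l + 1]])
    }
  img <- rand_gray(48, 48, seed = 22)
  ss2 <- build_scale_space(img, p)
  for (l in seq_along(ss2$dogs[[1]]))
    expect_equal(ss2$dogs[[1]][[l]] + ss2$gaussians[[1]][[l]],
                 ss2$gaussians[[1]][[l + 1]])
  expect_error(build_scale_space(matrix(0, 8, 8)),
               class = "dermoscan_domain_error")
  expect_error(build_scale_space(matrix(0, 32, 32), sift_params(octaves = 6)),
               class = "dermoscan_domain_error")
})

test_that("extremum detection equals exhaustive 26-neighbourhood enumeration", {
  for (s in 1:4) {
    img <- rand_gray(32, 32, seed = 30 + s, levels = 0:255)
    ss <- build_scale_space(img, sift_params(octaves = 1))
    found <- detect_extrema(ss)
    cube <- array(unlist(ss$dogs[[1]]),
                  dim = c(32, 32, length(ss$dogs[[1]])))
    want <- oracle_extrema(cube)
    got <- as.matrix(found[, c("i", "j", "level")])
    dimnames(got) <- NULL
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[order(got[, 3], got[, 2], got[, 1]), , drop = FALSE],
                   want[order(want[, 3], want[, 2], want[, 1]), , drop = FALSE])
    }
  }
})

test_that("a single bright blob yields a candidate at its position", {
  img <- blob_image(48, sigma = 3)
  ss <- build_scale_space(img, sift_params(octaves = 2))
  cand <- detect_extrema(ss)
  expect_gt(nrow(cand), 0)
  kp <- localize_and_filter(cand, ss)
  expect_gt(nrow(kp), 0)
  d <- sqrt((kp$x - 0.47 * 48)^2 + (kp$y - 0.52 * 48)^2)
  expect_lt(min(d), 2)
})

test_that("flat images and pure step edges produce no key points", {
  expect_equal(nrow(detect_keypoints(matrix(100, 64, 64),
                                     sift_params(octaves = 3))), 0)
  expect_equal(nrow(detect_keypoints(step_edge_image(64),
                                     sift_params(octaves = 3, r = 10))), 0)
})

test_that("an isotropic blob centre passes the edge-ratio test", {
  img <- blob_image(48, sigma = 4)
  ss <- build_scale_space(img, sift_params(octaves = 2))
  kp <- localize_and_filter(detect_extrema(ss), ss)
  expect_gt(nrow(kp), 0)   # survived det/trace screening with r = 10
})

test_that("gradient orientation histogram resolves ramps per the formulas", {
  n <- 21
  ramp_x <- matrix(rep(seq_len(n), each = n), n)    # L(x, y) = x
  ramp_y <- matrix(rep(seq_len(n), n), n)           # L(x, y) = y
  ss <- fake_ss(ramp_x)
  out <- assign_orientation(kp_row(11, 11), ss)
  expect_equal(nrow(out), 1)
  expect_lte(circular_dist(out$orientation, 0), pi / 36)   # phi = 0
  out_y <- assign_orientation(kp_row(11, 11), fake_ss(ramp_y))
  expect_lte(circular_dist(out_y$orientation, pi / 2), pi / 36)
})

test_that("descriptors are unit-norm, zero on constant patches, rotation-tolerant", {
  flat <- fake_ss(matrix(50, 40, 40))
  d0 <- compute_descriptor(kp_row(20, 20), flat)
  expect_equal(sum(d0$descriptor[[1]]^2), 0)
  set.seed(41)
  plane <- matrix(runif(1600, 0, 255), 40, 40)
  d1 <- compute_descriptor(kp_row(20, 20), fake_ss(plane))
  expect_equal(sqrt(sum(d1$descriptor[[1]]^2)), 1)
  # descriptor follows the assigned orientation: same blob, quarter-turned
  img <- blob_image(65, sigma = 4, aspect = 1.5)
  k1 <- detect_keypoints(img, sift_params(octaves = 2))
  k2 <- detect_keypoints(rot90cw(img), sift_params(octaves = 2))
  expect_gt(nrow(k1), 0); expect_gt(nrow(k2), 0)
  b1 <- k1[which.max(abs(k1$response)), ]
  b2 <- k2[which.max(abs(k2$response)), ]
  expect_lt(sqrt(sum((b1$descriptor[[1]] - b2$descriptor[[1]])^2)), 0.2)
})

test_that("key points are invariant to intensity doubling and 90-degree turns", {
  img <- blob_image(96, cx = 30, cy = 40, sigma = 4) / 2 +
    blob_image(96, cx = 70, cy = 65, sigma = 6) / 2
  p <- sift_params(octaves = 2)
  k1 <- detect_keypoints(img, p)
  k2 <- detect_keypoints(2 * img, p)      # intensities normalized per image
  expect_equal(k1[, c("x", "y", "sigma")], k2[, c("x", "y", "sigma")])
  k3 <- detect_keypoints(rot90cw(img), p)
  expect_lte(abs(nrow(k3) - nrow(k1)), max(1, ceiling(0.1 * nrow(k1))))
})

test_that("orientations shift by a quarter turn under image rotation", {
  img <- blob_image(65, sigma = 4, aspect = 1.5)
  p <- sift_params(octaves = 2)
  k1 <- detect_keypoints(img, p)
  k2 <- detect_keypoints(rot90cw(img), p)
  expect_gt(nrow(k1), 0); expect_gt(nrow(k2), 0)
  o1 <- k1$orientation[which.max(abs(k1$response))]
  o2 <- k2$orientation[which.max(abs(k2$response))]
  d <- (o2 - o1) %% (2 * pi)
  bin <- 2 * pi / p$orientation_bins
  expect_lte(min(abs(d - pi / 2), abs(d - 3 * pi / 2)), bin)
})
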