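make_kps <- function(x, y) tibble::tibble(x = x, y = y, sigma = 2,
                                          response = 1)

test_that("background filtering removes exact matches and keeps the rest", {
  img <- rand_rgb(20, 20, seed = 50)
  ref <- structure(list(
    entries = tibble::tibble(x = 5L, y = 7L,
                             R = img[7, 5, 1], G = img[7, 5, 2],
                             B = img[7, 5, 3]),
    dim = c(20L, 20L), source_count = 1L), class = "background_reference")
  kps <- make_kps(c(5, 12), c(7, 3))
  out <- filter_background(kps, img, ref)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 12)
  empty <- structure(list(entries = tibble::tibble(), dim = c(20L, 20L),
                          source_count = 1L), class = "background_reference")
  expect_identical(filter_background(kps, img, empty), kps)
})

test_that("reference building validates inputs and deduplicates", {
  expect_error(build_background_reference(list()),
               class = "dermoscan_domain_error")
  expect_error(build_background_reference(list(rand_rgb(20, 20), rand_rgb(24, 20))),
               class = "dermoscan_domain_error")
  # a poster-like dark square on a plain wall gives reproducible key points
  wall <- array(170, dim = c(64, 64, 3))
  wall[20:36, 20:36, ] <- 40
  p <- sift_params(octaves = 2)
  one <- build_background_reference(list(wall), p)
  twice <- build_background_reference(list(wall, wall), p)
  expect_gt(nrow(one$entries), 0)
  expect_identical(one$entries, twice$entries)
  # entries sit on the poster, the only structure in the frame
  expect_true(all(one$entries$x >= 16 & one$entries$x <= 40))
  expect_true(all(one$entries$y >= 16 & one$entries$y <= 40))
})

test_that("palette filter keeps matching colours and drops off-palette ones", {
  img <- array(0, dim = c(9, 9, 3))
  img[, 1:4, 1] <- 200; img[, 1:4, 2] <- 150; img[, 1:4, 3] <- 120
  img[, 5:9, 3] <- 255                       # pure blue right half
  kps <- make_kps(c(2, 7), c(5, 5))
  pal_exact <- skin_palette(matrix(c(200, 150, 120), 1), tolerance = 0)
  expect_equal(nrow(filter_palette(kps[1, ], img, pal_exact)), 1)
  pal_skin <- skin_palette(matrix(c(200, 150, 120), 1), tolerance = 30)
  out <- filter_palette(kps, img, pal_skin)
  expect_equal(out$x, 2)                     # blue key point removed
})

test_that("elongated-structure filter removes lines and keeps disks", {
  img <- array(200, dim = c(50, 50, 3))
  img[25, 5:44, ] <- 20                      # 1 x 40 dark line
  xs <- matrix(rep(1:50, each = 50), 50); ys <- matrix(rep(1:50, 50), 50)
  disk <- (xs - 12)^2 + (ys - 40)^2 <= 16
  for (c in 1:3) { ch <- img[, , c]; ch[disk] <- 20; img[, , c] <- ch }
  kps <- make_kps(c(25, 12), c(25, 40))      # on line, on disk
  out <- filter_elongated(kps, img, aspect_limit = 5, tol = 10)
  expect_equal(nrow(out), 1)
  expect_equal(out$x, 12)
})

test_that("filters are idempotent, order-preserving, and never add points", {
  scene <- make_scene(w = 400, h = 300, n_nevi = 2, clutter = 2, seed = 3)
  kps <- detect_keypoints(scene$image)
  pal <- default_skin_palette()
  f1 <- filter_palette(kps, scene$image, pal)
  expect_lte(nrow(f1), nrow(kps))
  expect_identical(filter_palette(f1, scene$image, pal), f1)
  f2 <- filter_elongated(f1, scene$image)
  expect_lte(nrow(f2), nrow(f1))
  expect_identical(filter_elongated(f2, scene$image), f2)
  # order preservation: survivors appear in their original order
  surv <- which(paste(kps$x, kps$y) %in% paste(f1$x, f1$y))
  expect_identical(paste(kps$x[surv], kps$y[surv]), paste(f1$x, f1$y))
})

test_that("background key points of a synthetic scene are recalled >= 0.95", {
  scene <- make_scene(w = 480, h = 360, n_nevi = 1, clutter = 3, seed = 7,
                      nevus_class = "benign")
  photos <- make_background_photos(scene, n = 2, lighting_jitter = 0)
  ref <- build_background_reference(photos)
  kps <- detect_keypoints(scene$image)
  # label as background only key points clearly inside the wall region: a
  # 10 px band along the skin/wall boundary has mixed support (blur mixes
  # both regions there) and is neither pure background nor pure skin
  band <- ceiling(0.55 * 480)
  on_wall <- round(kps$x) > band + 10
  expect_gt(sum(on_wall), 0)   # the clutter rectangles yield key points
  kept <- filter_background(kps, scene$image, ref, pos_tol = 2, color_tol = 20)
  kept_wall <- sum(round(kept$x) > band + 10)
  recall <- 1 - kept_wall / sum(on_wall)
  expect_gte(recall, 0.95)
})

test_that("palette and reference serialize to JSON and back", {
  pal <- skin_palette(rbind(c(1, 2, 3), c(200, 100, 50)), tolerance = 17)
  f <- withr::local_tempfile(fileext = ".json")
  write_skin_palette(pal, f)
  back <- read_skin_palette(f)
  expect_equal(back$colors, pal$colors)
  expect_equal(back$tolerance, 17)
  ref <- structure(list(entries = tibble::tibble(x = c(1L, 5L), y = c(2L, 6L),
                                                 R = c(0, 10), G = c(5, 20),
                                                 B = c(9, 30)),
                        dim = c(10L, 10L), source_count = 2L),
                   class = "background_reference")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_background_reference(ref, f2)
  back2 <- read_background_reference(f2)
  expect_equal(as.data.frame(back2$entries), as.data.frame(ref$entries))
  expect_equal(unlist(back2$dim), c(10, 10))
})
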