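hist4 <- function(g, r, gr, b) list(gray = g, R = r, G = gr, B = b)

test_that("histogram intersection behaves on toy distributions", {
  a <- hist4(c(2, 2, 0, 0), c(2, 2, 0, 0), c(2, 2, 0, 0), c(2, 2, 0, 0))
  b <- hist4(c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1), c(1, 1, 1, 1))
  expect_equal(histogram_similarity(a, a), 1)
  expect_equal(histogram_similarity(a, b), 0.5)   # sum min(.5,.25)*2 + 0.25*2
  disjoint <- hist4(c(0, 0, 3, 3), c(0, 0, 3, 3), c(0, 0, 3, 3), c(0, 0, 3, 3))
  expect_equal(histogram_similarity(a, disjoint), 0)
  expect_error(histogram_similarity(list(gray = 1:4), b),
               class = "dermoscan_domain_error")
})

test_that("similarity is symmetric, bounded, and 1 only at equality", {
  set.seed(81)
  for (q in 1:10) {
    a <- hist4(runif(16), runif(16), runif(16), runif(16))
    b <- hist4(runif(16), runif(16), runif(16), runif(16))
    s <- histogram_similarity(a, b)
    expect_equal(s, histogram_similarity(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
    expect_lt(s, 1)                               # random pairs never equal
    expect_equal(histogram_similarity(a, lapply(a, function(v) 3 * v)), 1)
  }
})

test_that("screening forwards nevus look-alikes and skips plain skin", {
  nevus_img <- rand_rgb(16, 16, seed = 82)
  skin_img <- array(210, dim = c(16, 16, 3))
  db <- build_nevus_database(list(nevus_img, skin_img), c("nevus", "skin"))
  cl_nevus <- structure(list(image = nevus_img, state = "raw"),
                        class = "dermo_cluster")
  cl_skin <- structure(list(image = skin_img, state = "raw"),
                       class = "dermo_cluster")
  s1 <- screen_cluster(cl_nevus, db, margin = 1)
  expect_true(s1$decision$forward)
  expect_equal(s1$decision$best_similarity_nevus, 1)
  expect_equal(s1$state, "screened")
  s2 <- screen_cluster(cl_skin, db, margin = 1)
  expect_false(s2$decision$forward)
  # degenerate configuration: nevus-only database at margin 0 forwards all
  db_n <- build_nevus_database(list(nevus_img), "nevus")
  expect_true(screen_cluster(cl_skin, db_n, margin = 0)$decision$forward)
  empty <- structure(list(entries = list(), version = "1"),
                     class = "nevus_database")
  expect_error(screen_cluster(cl_skin, empty), class = "dermoscan_state_error")
})

test_that("screening recall on generated clusters reaches 0.9", {
  ref <- make_cluster_dataset(15, seed = 100)
  db <- build_nevus_database(
    c(lapply(ref, `[[`, "image"), make_skin_patches(15, seed = 101)),
    c(rep("nevus", length(ref)), rep("skin", 15)))
  probe_nevi <- make_cluster_dataset(25, seed = 102)     # 50 nevus clusters
  probe_skin <- make_skin_patches(50, seed = 103)
  fwd_nevus <- vapply(probe_nevi, function(cl)
    screen_cluster(cl, db)$decision$forward, logical(1))
  expect_gte(mean(fwd_nevus), 0.9)
  fwd_skin <- vapply(probe_skin, function(img) {
    cl <- structure(list(image = img, state = "raw"), class = "dermo_cluster")
    screen_cluster(cl, db)$decision$forward
  }, logical(1))
  expect_lt(mean(fwd_skin), mean(fwd_nevus))   # skin is mostly skipped
})

test_that("cluster blurring applies the fixed kernel exactly", {
  expect_equal(blur_kernel(), matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16)
  const <- structure(list(image = array(93, dim = c(8, 8, 3)),
                          state = "screened",
                          decision = list(forward = TRUE)),
                     class = "dermo_cluster")
  expect_equal(blur_cluster(const)$image, array(93, dim = c(8, 8, 3)))
  # single white pixel spreads as 255 * kernel, rounded half up
  img <- array(0, dim = c(9, 9, 3))
  img[5, 5, ] <- 255
  cl <- structure(list(image = img, state = "screened",
                       decision = list(forward = TRUE)),
                  class = "dermo_cluster")
  out <- blur_cluster(cl)
  expect_equal(out$image[4:6, 4:6, 1],
               floor(255 * matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1), 3, 3) / 16 + 0.5))
  expect_equal(out$state, "blurred")
  # channel means preserved within rounding under the mass-1 kernel
  noisy <- structure(list(image = rand_rgb(12, 12, seed = 84),
                          state = "screened",
                          decision = list(forward = TRUE)),
                     class = "dermo_cluster")
  blurred <- blur_cluster(noisy)
  for (c in 1:3)
    expect_lte(abs(mean(blurred$image[, , c]) - mean(noisy$image[, , c])), 1)
  raw <- structure(list(image = img, state = "raw"), class = "dermo_cluster")
  expect_error(blur_cluster(raw), class = "dermoscan_state_error")
})

test_that("the exemplar database survives a JSON round trip", {
  db <- build_nevus_database(list(rand_rgb(8, 8, seed = 85),
                                  array(200, dim = c(8, 8, 3))),
                             c("nevus", "skin"))
  f <- withr::local_tempfile(fileext = ".json")
  write_nevus_database(db, f)
  back <- read_nevus_database(f)
  expect_equal(length(back$entries), 2)
  expect_equal(back$entries[[1]]$label, "nevus")
  expect_equal(back$entries[[1]]$hist$gray, db$entries[[1]]$hist$gray)
  probe <- structure(list(image = rand_rgb(8, 8, seed = 85), state = "raw"),
                     class = "dermo_cluster")
  expect_equal(screen_cluster(probe, back)$decision,
               screen_cluster(probe, db)$decision)
})
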