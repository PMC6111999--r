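#' Nevus exemplar database
#'
#' Stores unit-normalized gray/R/G/B histogram sets of exemplar images
#' labelled `"nevus"` or `"skin"`. Incoming clusters are compared against
#' both groups; only clusters that look more like a stored nevus than like
#' plain skin are forwarded to the classifier.
#'
#' @param images list of RGB arrays (e.g. cluster images).
#' @param labels character vector, one of `"nevus"` / `"skin"` per image.
#' @param version free-form version string.
#' @return A list of class `nevus_database`.
#' @export
build_nevus_database <- function(images, labels, version = "1") {
  stopifnot(length(images) == length(labels))
  if (!all(labels %in% c("nevus", "skin")))
    stop_domain("labels must be 'nevus' or 'skin'")
  entries <- purrr::map2(images, labels, function(img, lab) {
    list(hist = lapply(hist_set(img), function(v) v / sum(v)), label = lab)
  })
  structure(list(entries = entries, version = version),
            class = "nevus_database")
}

#' @rdname build_nevus_database
#' @param db a `nevus_database`.
#' @param path JSON file path.
#' @export
write_nevus_database <- function(db, path) {
  jsonlite::write_json(
    list(version = db$version,
         entries = lapply(db$entries, function(e)
           list(label = e$label, hist = e$hist))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname build_nevus_database
#' @export
read_nevus_database <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- lapply(seq_len(nrow(j$entries)), function(n) {
    list(hist = list(gray = j$entries$hist$gray[[n]],
                     R = j$entries$hist$R[[n]],
                     G = j$entries$hist$G[[n]],
                     B = j$entries$hist$B[[n]]),
         label = j$entries$label[[n]])
  })
  structure(list(entries = entries, version = j$version),
            class = "nevus_database")
}

# accept a histogram set as a named list of count vectors or the long tibble
# produced by histograms()
canonical_hist_set <- function(x) {
  if (is.data.frame(x)) {
    x <- split(x$count, x$channel)
  }
  need <- c("gray", "R", "G", "B")
  if (!all(need %in% names(x))) stop_domain("histogram set needs gray, R, G, B")
  lapply(x[need], function(v) {
    s <- sum(v)
    if (s > 0) v / s else v
  })
}

#' Histogram-set similarity
#'
#' Mean over the gray, R, G and B channels of the histogram intersection
#' `sum(min(a_i, b_i))` on unit-normalized histograms. Symmetric, bounded in
#' `[0, 1]`, and 1 exactly when the normalized sets are equal.
#'
#' @param a,b histogram sets: named lists of per-channel count vectors, or
#'   tibbles as returned by [histograms()].
#' @return A number in `[0, 1]`.
#' @export
histogram_similarity <- function(a, b) {
  a <- canonical_hist_set(a); b <- canonical_hist_set(b)
  mean(vapply(names(a), function(ch) {
    if (length(a[[ch]]) != length(b[[ch]]))
      stop_domain("histogram lengths differ")
    sum(pmin(a[[ch]], b[[ch]]))
  }, numeric(1)))
}

#' Screen one cluster against the exemplar database
#'
#' Computes the best histogram similarity of the (un-blurred) cluster against
#' the nevus-labelled and skin-labelled exemplars. The cluster is forwarded
#' when `best_nevus >= best_skin * margin`, or when the two similarities are
#' within `inconclusive` of each other (an ambiguous cluster is forwarded:
#' the system favours sensitivity).
#'
#' @param cluster a `dermo_cluster`.
#' @param db a [build_nevus_database()] result with at least one entry per
#'   label.
#' @param margin forwarding margin (>= 0); default 1 forwards iff the nevus
#'   similarity is at least the skin similarity.
#' @param inconclusive similarity gap below which the decision is considered
#'   ambiguous and the cluster forwarded anyway.
#' @return The cluster with `state = "screened"` and a `decision` element
#'   (`forward`, `best_similarity_nevus`, `best_similarity_skin`).
#' @export
screen_cluster <- function(cluster, db, margin = 1, inconclusive = 0.02) {
  if (length(db$entries) == 0) stop_state("nevus database is empty")
  labs <- vapply(db$entries, function(e) e$label, character(1))
  hs <- canonical_hist_set(hist_set(cluster$image))
  sims <- vapply(db$entries, function(e) histogram_similarity(hs, e$hist),
                 numeric(1))
  best_nevus <- if (any(labs == "nevus")) max(sims[labs == "nevus"]) else 0
  best_skin <- if (any(labs == "skin")) max(sims[labs == "skin"]) else 0
  forward <- best_nevus >= best_skin * margin ||
    abs(best_nevus - best_skin) < inconclusive
  cluster$decision <- list(forward = forward,
                           best_similarity_nevus = best_nevus,
                           best_similarity_skin = best_skin)
  cluster$state <- "screened"
  cluster
}

#' Blur a forwarded cluster
#'
#' Convolves each colour channel with the fixed Gaussian blur kernel
#' `(1/16) [1 2 1; 2 4 2; 1 2 1]` (edge replication, round half up) before
#' the cluster is handed to the classifier.
#'
#' @param cluster a screened, forwarded `dermo_cluster`.
#' @return The cluster with blurred `image` and `state = "blurred"`.
#' @export
blur_cluster <- function(cluster) {
  if (!identical(cluster$state, "screened"))
    stop_state("cluster must be screened before blurring")
  k <- blur_kernel()
  img <- cluster$image
  for (c in 1:3) img[, , c] <- clamp255(round_half_up(
    conv2d_replicate_cpp(cluster$image[, , c], k)))
  cluster$image <- img
  cluster$state <- "blurred"
  cluster
}

#' Fixed named kernels
#'
#' `blur_kernel()` is the 3 x 3 Gaussian blur `(1/16) [1 2 1; 2 4 2; 1 2 1]`;
#' `emboss_kernel()` is the relief filter
#' `[-2 -1 0; -1 1 1; 0 1 2]` (entries sum to 1, so constant planes are
#' unchanged).
#'
#' @return A 3 x 3 numeric matrix.
#' @export
blur_kernel <- function() matrix(c(1, 2, 1, 2, 4, 2, 1, 2, 1) / 16, 3, 3)

#' @rdname blur_kernel
#' @export
emboss_kernel <- function() matrix(c(-2, -1, 0, -1, 1, 1, 0, 1, 2), 3, 3,
                                   byrow = TRUE)
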