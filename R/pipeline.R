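#' Pipeline configuration
#'
#' One nested list holding every tunable of the pipeline; individual
#' entries can be overridden via `overrides` (named sublists) or loaded
#' from a YAML/JSON file with [read_config()].
#'
#' @param overrides named list of sublists to merge over the defaults.
#' @return A list of class `dermoscan_config` with elements `sift`,
#'   `cluster`, `background` (`pos_tol`, `color_tol`), `elongated`
#'   (`aspect_limit`, `tol`), `screening` (`margin`, `inconclusive`),
#'   `training`, and `palette`.
#' @export
dermoscan_config <- function(overrides = list()) {
  cfg <- list(
    sift = sift_params(),
    cluster = cluster_params(),
    background = list(pos_tol = 2, color_tol = 20),
    elongated = list(aspect_limit = 5, tol = 10),
    screening = list(margin = 1, inconclusive = 0.02),
    training = training_config(),
    palette = default_skin_palette()
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][[k]] <- overrides[[nm]][[k]]
    } else cfg[[nm]] <- overrides[[nm]]
  }
  structure(cfg, class = "dermoscan_config")
}

#' @rdname dermoscan_config
#' @param path YAML or JSON config file.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_format("YAML configs require the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  dermoscan_config(raw)
}

#' Analyze one photograph end to end
#'
#' Runs the full chain: key-point detection, background/palette/elongation
#' filtering, cluster extraction, histogram screening, blurring and
#' classification. Per-stage survivor counts are recorded. Any stage
#' failure yields a report with an error status and no alert.
#'
#' @param img RGB array.
#' @param model a trained [cnn_model()].
#' @param db a [build_nevus_database()] with both labels present.
#' @param ref optional [build_background_reference()]; `NULL` skips the
#'   background filter.
#' @param config a [dermoscan_config()].
#' @param image_id identifier recorded in the report.
#' @param store optional directory; when given, the report is persisted
#'   there as JSON.
#' @return A list of class `analysis_report`: `image_id`, `status`,
#'   `alert` (TRUE iff any cluster is classified suspicious), a `clusters`
#'   tibble (key point, screening decision, label and score per cluster),
#'   `counts` of stage survivors, `timestamp`, and the cluster objects.
#' @export
analyze_image <- function(img, model, db, ref = NULL,
                          config = dermoscan_config(), image_id = "image",
                          store = NULL) {
  report <- tryCatch({
    kps <- detect_keypoints(img, config$sift)
    n0 <- nrow(kps)
    if (!is.null(ref))
      kps <- filter_background(kps, img, ref, config$background$pos_tol,
                               config$background$color_tol)
    n1 <- nrow(kps)
    kps <- filter_palette(kps, img, config$palette)
    kps <- filter_elongated(kps, img, config$elongated$aspect_limit,
                            config$elongated$tol)
    n2 <- nrow(kps)
    clusters <- clusters_from_image(img, kps, config$cluster)
    n3 <- length(clusters)
    clusters <- lapply(clusters, screen_cluster, db = db,
                       margin = config$screening$margin,
                       inconclusive = config$screening$inconclusive)
    empty_rows <- tibble(
      x = numeric(), y = numeric(), sigma = numeric(), response = numeric(),
      region_size = integer(), forwarded = logical(),
      similarity_nevus = numeric(), similarity_skin = numeric(),
      xmin = integer(), ymin = integer(), xmax = integer(), ymax = integer(),
      label = character(), score = numeric())
    rows <- purrr::map_dfr(clusters, function(cl) {
      kp <- cl$source_keypoint
      row <- tibble(x = kp$x, y = kp$y,
                    sigma = kp$sigma %||% NA_real_,
                    response = kp$response %||% NA_real_,
                    region_size = cl$region_size,
                    forwarded = cl$decision$forward,
                    similarity_nevus = cl$decision$best_similarity_nevus,
                    similarity_skin = cl$decision$best_similarity_skin,
                    xmin = cl$bbox_full[1], ymin = cl$bbox_full[2],
                    xmax = cl$bbox_full[3], ymax = cl$bbox_full[4],
                    label = NA_character_, score = NA_real_)
      row
    })
    if (nrow(rows) == 0) rows <- empty_rows
    forwarded <- which(vapply(clusters, function(cl) cl$decision$forward,
                              logical(1)))
    for (q in forwarded) {
      clusters[[q]] <- blur_cluster(clusters[[q]])
      pr <- predict(model, clusters[[q]])
      rows$label[q] <- pr$label
      rows$score[q] <- pr$score
    }
    list(image_id = image_id, status = "ok",
         alert = any(rows$label == "suspicious", na.rm = TRUE),
         clusters = rows,
         counts = c(keypoints = n0, after_background = n1, after_filters = n2,
                    clusters = n3, forwarded = length(forwarded)),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         cluster_objects = clusters)
  }, error = function(e) {
    list(image_id = image_id, status = "error",
         error = conditionMessage(e), alert = FALSE,
         clusters = tibble(), counts = c(),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         cluster_objects = list())
  })
  report <- structure(report, class = "analysis_report")
  if (!is.null(store)) {
    dir.create(store, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report[c("image_id", "status", "alert", "clusters", "counts",
               "timestamp")],
      file.path(store, paste0(image_id, ".json")),
      auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Confusion counts and quality measures
#'
#' Counts TP/TN/FP/FN of `predictions` against `truth` for the given
#' positive class and derives the nine standard measures: accuracy
#' `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, fall-out `FP/(FP+TN)`, false negative rate
#' `FN/(FN+TP)`, negative predictive rate `TN/(TN+FN)`, false discovery
#' rate `FP/(FP+TP)` and F-measure `2 P Se / (P + Se)`. Ratios with a zero
#' denominator are reported as `NA`, never 0.
#'
#' @param predictions character vector of predicted labels.
#' @param truth character vector of true labels, same length.
#' @param positive_class the label counted as positive.
#' @return A list of class `dermo_eval` with `counts` (named TP/TN/FP/FN)
#'   and `metrics` (one-row tibble).
#' @export
evaluate_predictions <- function(predictions, truth,
                                 positive_class = "suspicious") {
  if (length(predictions) != length(truth) || length(truth) < 1)
    stop_domain("predictions and truth must have equal positive length")
  tp <- sum(predictions == positive_class & truth == positive_class)
  tn <- sum(predictions != positive_class & truth != positive_class)
  fp <- sum(predictions == positive_class & truth != positive_class)
  fn <- sum(predictions != positive_class & truth == positive_class)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  p <- ratio(tp, tp + fp); se <- ratio(tp, tp + fn)
  metrics <- tibble(
    accuracy = ratio(tp + tn, tp + tn + fp + fn),
    precision = p,
    sensitivity = se,
    specificity = ratio(tn, tn + fp),
    fall_out = ratio(fp, fp + tn),
    false_negative_rate = ratio(fn, fn + tp),
    negative_predictive_rate = ratio(tn, tn + fn),
    false_discovery_rate = ratio(fp, fp + tp),
    f_measure = f_measure(p, se)
  )
  structure(list(counts = c(TP = tp, TN = tn, FP = fp, FN = fn),
                 metrics = metrics, positive_class = positive_class),
            class = "dermo_eval")
}

#' Harmonic mean of precision and sensitivity
#'
#' @param precision,sensitivity values in `[0, 1]`.
#' @return `2 * precision * sensitivity / (precision + sensitivity)`, or
#'   `NA` when undefined.
#' @export
f_measure <- function(precision, sensitivity) {
  if (is.na(precision) || is.na(sensitivity) ||
      precision + sensitivity == 0) return(NA_real_)
  2 * precision * sensitivity / (precision + sensitivity)
}

blur_rgb <- function(img) {
  k <- blur_kernel()
  for (c in 1:3) img[, , c] <- clamp255(round_half_up(
    conv2d_replicate_cpp(img[, , c], k)))
  img
}

#' Train/test experiment on a labelled cluster set
#'
#' Stratified seeded train/test split (default 70/30), training via
#' [train_cnn()] on blurred cluster images (the classifier always consumes
#' blurred clusters, as in the live pipeline), and evaluation of the held-out
#' set via [evaluate_predictions()]. Optionally writes a metrics CSV and a
#' confusion-matrix JSON.
#'
#' @param data list of labelled clusters; defaults to a synthetic dataset of
#'   `n_per_class` per label.
#' @param n_per_class size of the default synthetic dataset.
#' @param split training fraction in (0, 1).
#' @param seed seed controlling the dataset, the split and the weights.
#' @param cfg a [training_config()]; its seed is taken from `seed`.
#' @param model a `cnn_model` to train; default architecture if `NULL`.
#' @param out_dir optional output directory for `metrics.csv` and
#'   `confusion.json`.
#' @return A list of class `dermo_experiment`: `eval` (a `dermo_eval`),
#'   `model`, `n_train`, `n_test`.
#' @export
run_experiment <- function(data = NULL, n_per_class = 50, split = 0.7,
                           seed = 0, cfg = NULL, model = NULL,
                           out_dir = NULL) {
  stopifnot(split > 0, split < 1)
  if (is.null(data))
    data <- make_cluster_dataset(n_per_class, seed = seed)
  if (is.null(cfg)) cfg <- training_config(seed = seed)
  cfg$seed <- as.integer(seed)
  data <- lapply(data, function(cl) { cl$image <- blur_rgb(cl$image); cl })
  labs <- vapply(data, sample_label, character(1))
  set.seed(seed)
  train_idx <- unlist(lapply(unique(labs), function(l) {
    idx <- which(labs == l)
    sample(idx, round(split * length(idx)))
  }))
  test_idx <- setdiff(seq_along(data), train_idx)
  if (length(test_idx) == 0) stop_domain("empty test split")
  dim1 <- dim(data[[1]]$image)
  if (is.null(model))
    model <- cnn_model(input_dim = c(dim1[1], dim1[2], 4L))
  model <- train_cnn(model, data[train_idx], cfg)
  preds <- predict(model, data[test_idx])
  ev <- evaluate_predictions(preds$label, labs[test_idx])
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ev$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(as.list(ev$counts), file.path(out_dir, "confusion.json"),
                         auto_unbox = TRUE)
  }
  structure(list(eval = ev, model = model,
                 n_train = length(train_idx), n_test = length(test_idx)),
            class = "dermo_experiment")
}

parse_ph2_index <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list()
  for (ln in lines) {
    if (!grepl("IMD", ln)) next
    fields <- trimws(strsplit(ln, "\\|")[[1]])
    fields <- fields[fields != ""]
    name <- grep("^IMD[0-9]+$", fields, value = TRUE)
    if (length(name) != 1) next
    diag <- grep("^[012]$", fields, value = TRUE)
    if (length(diag) < 1) next
    rows[[length(rows) + 1]] <- tibble(name = name,
                                       diagnosis = as.integer(diag[1]))
  }
  dplyr::bind_rows(rows)
}

#' Load a PH2-layout dermoscopy directory as labelled clusters
#'
#' Expects the archive layout of per-lesion folders
#' (`<id>/<id>_Dermoscopic_Image/<id>.bmp`) plus an index file
#' (`PH2_dataset.txt` with `||`-separated rows, or a `PH2_dataset.csv` with
#' `name,diagnosis` columns). Clinical diagnosis 0 (common nevus) and 1
#' (atypical nevus) map to `benign`; 2 (melanoma) maps to `suspicious`.
#' Images are resized to the cluster size.
#'
#' @param dir dataset root directory.
#' @param target_dim `c(width, height)` of the returned cluster images.
#' @return List of labelled `dermo_cluster` objects (fields `image`,
#'   `label`, `name`).
#' @export
load_ph2 <- function(dir, target_dim = c(64L, 64L)) {
  if (!dir.exists(dir)) stop_format(paste0("no such directory: ", dir))
  idx_txt <- file.path(dir, "PH2_dataset.txt")
  idx_csv <- file.path(dir, "PH2_dataset.csv")
  index <- if (file.exists(idx_txt)) parse_ph2_index(idx_txt)
    else if (file.exists(idx_csv)) {
      d <- utils::read.csv(idx_csv, stringsAsFactors = FALSE)
      tibble(name = d$name, diagnosis = as.integer(d$diagnosis))
    } else stop_format("missing index file (PH2_dataset.txt or PH2_dataset.csv)")
  if (nrow(index) == 0) stop_format("index file contains no entries")
  roots <- c(dir, file.path(dir, "PH2 Dataset images"))
  missing <- character()
  out <- list()
  for (n in seq_len(nrow(index))) {
    name <- index$name[n]
    cand <- file.path(roots, name, paste0(name, "_Dermoscopic_Image"),
                      paste0(name, ".bmp"))
    path <- cand[file.exists(cand)][1]
    if (is.na(path)) { missing <- c(missing, name); next }
    img <- resize_image(load_image(path), target_dim[1], target_dim[2])
    label <- if (index$diagnosis[n] >= 2) "suspicious" else "benign"
    out[[length(out) + 1]] <- structure(
      list(image = img, label = label, name = name, state = "raw"),
      class = "dermo_cluster")
  }
  if (length(missing) > 0)
    stop_format(paste0("missing image files for: ",
                       paste(missing, collapse = ", ")))
  out
}
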