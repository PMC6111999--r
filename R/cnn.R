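#' Layer constructors
#'
#' Building blocks of the classifier. Convolutional layers hold `filters`
#' kernels of odd side `size` (one kernel spans all input channels) applied
#' as valid-region convolution with step `stride`, so an `N x N` plane maps
#' to side `floor((N - size) / stride) + 1`. Fixed kernels (e.g.
#' [blur_kernel()], [emboss_kernel()]) may be supplied and optionally frozen.
#' Pooling layers replace each non-overlapping 3 x 3 tile by one value —
#' the tile maximum (`plain_max`) or the weighted colour maximum
#' `mu1 maxR + mu2 maxG + mu3 maxB` (`weighted_color_max`, weights summing
#' to 1) — and hold no trainable parameters. Dense layers compute
#' `y_k = tanh(sum_j w_jk x_j)` (no bias), so every output lies in (-1, 1).
#'
#' @param filters number of kernels.
#' @param size odd kernel side.
#' @param stride positive step.
#' @param kernels optional `size x size x C x filters` array (or a single
#'   `size x size` matrix recycled over channels) of fixed initial weights.
#' @param trainable whether the layer's weights are updated during training.
#' @return A layer spec list.
#' @name cnn-layers
NULL

#' @rdname cnn-layers
#' @export
conv_layer <- function(filters, size = 3L, stride = 1L, kernels = NULL,
                       trainable = TRUE) {
  stopifnot(filters >= 1, size %% 2 == 1, stride >= 1)
  list(type = "conv", filters = as.integer(filters), size = as.integer(size),
       stride = as.integer(stride), kernels = kernels, trainable = trainable)
}

#' @rdname cnn-layers
#' @param mode pooling mode.
#' @param mu three weights for `weighted_color_max`, summing to 1.
#' @export
pool_layer <- function(mode = c("plain_max", "weighted_color_max"),
                       mu = c(1, 1, 1) / 3) {
  mode <- match.arg(mode)
  if (mode == "weighted_color_max" && abs(sum(mu) - 1) > 1e-12)
    stop_domain("mu weights must sum to 1")
  list(type = "pool", mode = mode, mu = mu, trainable = FALSE)
}

#' @rdname cnn-layers
#' @param units number of output neurons.
#' @export
dense_layer <- function(units) {
  stopifnot(units >= 1)
  list(type = "dense", units = as.integer(units), trainable = TRUE)
}

default_architecture <- function() list(
  conv_layer(8), pool_layer(), conv_layer(16), pool_layer(),
  dense_layer(32), dense_layer(2)
)

#' Convolutional network model
#'
#' Assembles a layer stack and resolves all shapes. The default architecture
#' is conv(8) - pool - conv(16) - pool - dense(32) - dense(2) on a
#' `64 x 64 x 4` input (the gray plane plus the R, G, B planes of a cluster
#' image, each scaled to `[0, 1]`). Output unit 1 codes benign, unit 2
#' suspicious. Weights are unset until [train_cnn()] initializes them.
#'
#' @param input_dim `c(height, width, channels)` of the input planes.
#' @param layers list of layer specs ([conv_layer()], [pool_layer()],
#'   [dense_layer()]); the last layer must be `dense(2)`.
#' @return A list of class `cnn_model`.
#' @export
cnn_model <- function(input_dim = c(64L, 64L, 4L),
                      layers = default_architecture()) {
  shape <- as.integer(input_dim)
  for (li in seq_along(layers)) {
    l <- layers[[li]]
    if (l$type == "conv") {
      if (length(shape) != 3 || l$size > min(shape[1:2]))
        stop_domain("kernel larger than input plane")
      out_side <- function(n) (n - l$size) %/% l$stride + 1L
      layers[[li]]$in_shape <- shape
      layers[[li]]$wdim <- c(l$size, l$size, shape[3], l$filters)
      shape <- c(out_side(shape[1]), out_side(shape[2]), l$filters)
    } else if (l$type == "pool") {
      if (length(shape) != 3) stop_domain("pooling needs image planes")
      if (l$mode == "weighted_color_max" && shape[3] != 3)
        stop_domain("weighted_color_max pooling needs exactly 3 channels")
      layers[[li]]$in_shape <- shape
      oc <- if (l$mode == "weighted_color_max") 1L else shape[3]
      shape <- c((shape[1] + 2L) %/% 3L, (shape[2] + 2L) %/% 3L, oc)
    } else {
      layers[[li]]$in_shape <- shape
      layers[[li]]$n_in <- as.integer(prod(shape))
      shape <- l$units
    }
    layers[[li]]$out_shape <- shape
  }
  last <- layers[[length(layers)]]
  if (last$type != "dense" || last$units != 2L)
    stop_domain("the final layer must be dense with 2 outputs")
  structure(list(input_dim = as.integer(input_dim), layers = layers,
                 n_outputs = 2L, trained = FALSE, seed = NA_integer_,
                 history = NULL),
            class = "cnn_model")
}

init_weights <- function(model) {
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      if (!is.null(l$kernels)) {
        k <- l$kernels
        if (is.matrix(k)) k <- array(rep(k, l$wdim[3] * l$wdim[4]), dim = l$wdim)
        stopifnot(all(dim(k) == l$wdim))
        model$layers[[li]]$weights <- k
      } else {
        model$layers[[li]]$weights <- array(runif(prod(l$wdim), -0.1, 0.1),
                                            dim = l$wdim)
      }
    } else if (l$type == "dense") {
      model$layers[[li]]$weights <- matrix(runif(l$n_in * l$units, -0.1, 0.1),
                                           l$n_in, l$units)
    }
  }
  model
}

#' Forward primitives
#'
#' `conv_forward()` applies valid-region multi-channel convolution,
#' `pool_forward()` 3 x 3 pooling, `dense_forward()` one tanh layer. These
#' are the building blocks the model forward pass is made of, exported for
#' inspection and testing.
#'
#' @param x input: `h x w x C` array (conv/pool) or numeric vector (dense).
#' @param weights `m x m x C x F` kernel array (a bare `m x m` matrix is
#'   promoted to one single-channel filter), or an `n_in x units` matrix for
#'   `dense_forward`.
#' @param stride convolution step.
#' @return The transformed planes or vector.
#' @export
conv_forward <- function(x, weights, stride = 1L) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (is.matrix(weights)) weights <- array(weights, dim = c(dim(weights), 1L, 1L))
  if (dim(weights)[1] > min(dim(x)[1:2])) stop_domain("kernel larger than plane")
  if (dim(weights)[3] != dim(x)[3]) stop_domain("channel mismatch")
  conv_stack_valid_cpp(as.numeric(x), dim(x), as.numeric(weights),
                       dim(weights), as.integer(stride))
}

#' @rdname conv_forward
#' @param spec a [pool_layer()] spec.
#' @export
pool_forward <- function(x, spec = pool_layer()) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  p <- pool3_forward_cpp(as.numeric(x), dim(x))
  if (spec$mode == "plain_max") return(p$out)
  if (dim(x)[3] != 3) stop_domain("weighted_color_max pooling needs 3 channels")
  o <- p$out
  array(spec$mu[1] * o[, , 1] + spec$mu[2] * o[, , 2] + spec$mu[3] * o[, , 3],
        dim = c(dim(o)[1:2], 1L))
}

#' @rdname conv_forward
#' @export
dense_forward <- function(x, weights) {
  if (length(x) != nrow(weights)) stop_domain("input size mismatch")
  tanh(as.numeric(crossprod(weights, x)))
}

# full forward pass with per-layer caches for backpropagation
forward_cnn <- function(model, x) {
  caches <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$type == "conv") {
      caches[[li]] <- list(x = x)
      x <- conv_stack_valid_cpp(as.numeric(x), dim(x), as.numeric(l$weights),
                                dim(l$weights), l$stride)
    } else if (l$type == "pool") {
      p <- pool3_forward_cpp(as.numeric(x), dim(x))
      caches[[li]] <- list(idim = dim(x), odim = dim(p$out),
                           arg_i = p$arg_i, arg_j = p$arg_j)
      x <- if (l$mode == "weighted_color_max")
        array(l$mu[1] * p$out[, , 1] + l$mu[2] * p$out[, , 2] +
                l$mu[3] * p$out[, , 3], dim = c(dim(p$out)[1:2], 1L))
      else p$out
    } else {
      xin <- as.numeric(x)
      y <- tanh(as.numeric(crossprod(l$weights, xin)))
      caches[[li]] <- list(xin = xin, y = y, adim = dim(x))
      x <- y
    }
  }
  list(y = x, caches = caches)
}

target_vector <- function(label) {
  if (label == "benign") c(0.9, -0.9) else c(-0.9, 0.9)
}

# turn a cluster / image into the model's input planes, scaled to [0, 1]
as_cnn_input <- function(obj, input_dim) {
  img <- if (is.list(obj) && !is.null(obj$image)) obj$image else obj
  if (is.matrix(img)) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (!all(dim(img)[1:2] == input_dim[1:2]))
    stop_domain("cluster image does not match the model input size")
  ch <- input_dim[3]
  x <- array(0, dim = input_dim)
  if (ch == 1L) {
    x[, , 1] <- to_gray(img) / 255
  } else if (ch == 3L) {
    x <- img / 255
  } else if (ch == 4L) {
    x[, , 1] <- to_gray(img) / 255
    x[, , 2:4] <- img / 255
  } else stop_domain("unsupported channel count")
  x
}

sample_label <- function(obj) {
  lab <- if (is.list(obj)) obj$label else NULL
  if (is.null(lab)) stop_domain("training sample lacks a label")
  if (!lab %in% c("benign", "suspicious"))
    stop_domain("labels must be 'benign' or 'suspicious'")
  lab
}

#' Loss and analytic gradients
#'
#' `cnn_loss()` evaluates the mean squared-error loss
#' `0.5 sum_k (y_k - t_k)^2` (targets +/- 0.9 on the two tanh outputs),
#' averaged over the batch. `cnn_gradients()` additionally backpropagates it
#' through the stack by the chain rule: dense layers via
#' `d f / d x = d f / d y * phi'(x)` with `phi' = 1 - tanh^2`, convolutional
#' kernels via the valid-convolution adjoint, and pooling layers by routing
#' each gradient to its argmax source pixel (pooling holds no trainable
#' weights).
#'
#' @param model an initialized `cnn_model`.
#' @param batch list of labelled samples (clusters or lists with `image` and
#'   `label`).
#' @return `cnn_loss`: a number. `cnn_gradients`: list with `loss` and
#'   `grads` (per-layer weight gradients, `NULL` for pooling layers).
#' @export
cnn_loss <- function(model, batch) {
  mean(vapply(batch, function(s) {
    y <- forward_cnn(model, as_cnn_input(s, model$input_dim))$y
    0.5 * sum((y - target_vector(sample_label(s)))^2)
  }, numeric(1)))
}

#' @rdname cnn_loss
#' @export
cnn_gradients <- function(model, batch) {
  grads <- lapply(model$layers, function(l) {
    if (l$type == "conv") array(0, dim = l$wdim)
    else if (l$type == "dense") matrix(0, l$n_in, l$units)
    else NULL
  })
  total <- 0
  for (s in batch) {
    fw <- forward_cnn(model, as_cnn_input(s, model$input_dim))
    t <- target_vector(sample_label(s))
    total <- total + 0.5 * sum((fw$y - t)^2)
    dy <- fw$y - t
    for (li in rev(seq_along(model$layers))) {
      l <- model$layers[[li]]
      cc <- fw$caches[[li]]
      if (l$type == "dense") {
        da <- dy * (1 - cc$y^2)
        grads[[li]] <- grads[[li]] + outer(cc$xin, da)
        dy <- as.numeric(l$weights %*% da)
        if (!is.null(cc$adim)) dy <- array(dy, dim = cc$adim)
      } else if (l$type == "pool") {
        dout <- dy
        if (l$mode == "weighted_color_max") {
          d3 <- array(0, dim = cc$odim)
          for (c in 1:3) d3[, , c] <- l$mu[c] * dout[, , 1]
          dout <- d3
        }
        dy <- pool3_backward_cpp(as.numeric(dout), cc$arg_i, cc$arg_j,
                                 cc$idim, cc$odim)
      } else {
        bk <- conv_stack_backward_cpp(as.numeric(cc$x), dim(cc$x),
                                      as.numeric(l$weights), dim(l$weights),
                                      as.numeric(dy), l$stride)
        grads[[li]] <- grads[[li]] + bk$dweights
        dy <- bk$dinput
      }
    }
  }
  n <- length(batch)
  list(loss = total / n,
       grads = lapply(grads, function(g) if (is.null(g)) NULL else g / n))
}

#' Training configuration
#'
#' @param learning_rate gradient-descent step size (> 0).
#' @param epochs passes over the data (>= 1).
#' @param batch_size mini-batch size (>= 1).
#' @param seed RNG seed for weight initialization and shuffling.
#' @return A list of class `training_config`.
#' @export
training_config <- function(learning_rate = 0.05, epochs = 30L,
                            batch_size = 16L, seed = 0L) {
  stopifnot(learning_rate > 0, epochs >= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "training_config")
}

#' One gradient-descent step
#'
#' Computes analytic gradients over the batch and updates every trainable
#' layer by `w <- w - learning_rate * grad`. Training aborts with a
#' diagnostic when the loss is not finite.
#'
#' @param model an initialized `cnn_model`.
#' @param batch list of labelled samples.
#' @param cfg a [training_config()].
#' @return List with the updated `model` and the batch `loss` (measured
#'   before the update).
#' @export
backprop_step <- function(model, batch, cfg = training_config()) {
  g <- cnn_gradients(model, batch)
  if (!is.finite(g$loss))
    stop_state(paste0("training aborted: non-finite loss (", g$loss, ")"))
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (isTRUE(l$trainable) && !is.null(g$grads[[li]]))
      model$layers[[li]]$weights <- l$weights - cfg$learning_rate * g$grads[[li]]
  }
  list(model = model, loss = g$loss)
}

#' Train the classifier
#'
#' Initializes all weights from a seeded uniform(-0.1, 0.1) draw, then runs
#' `epochs` passes of shuffled mini-batch gradient descent. Fully
#' reproducible for a fixed seed.
#'
#' @param model a `cnn_model`.
#' @param data list of labelled samples; both classes must be present.
#' @param cfg a [training_config()].
#' @return The trained model, with a `history` tibble (`epoch`, `loss`).
#' @export
train_cnn <- function(model, data, cfg = training_config()) {
  labs <- vapply(data, sample_label, character(1))
  if (length(unique(labs)) < 2)
    stop_domain("training data must contain both classes")
  set.seed(cfg$seed)
  model <- init_weights(model)
  history <- numeric(cfg$epochs)
  n <- length(data)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    losses <- c()
    for (b in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
      st <- backprop_step(model, data[b], cfg)
      model <- st$model
      losses <- c(losses, st$loss)
    }
    history[ep] <- mean(losses)
  }
  model$trained <- TRUE
  model$seed <- cfg$seed
  model$history <- tibble(epoch = seq_len(cfg$epochs), loss = history)
  model
}

#' Classify clusters
#'
#' Maps the two tanh outputs to `[0, 1]` via `(y + 1) / 2`, renormalizes
#' them to sum 1, and labels by the larger class probability; an exact tie
#' is resolved as benign (with a warning). `score` is the suspicious-class
#' probability.
#'
#' @param object a trained `cnn_model`.
#' @param newdata one cluster/sample or a list of them.
#' @param ... unused.
#' @return Tibble with one row per input: `label`, `score`, `p_benign`,
#'   `p_suspicious`.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  if (!isTRUE(object$trained)) stop_state("model has not been trained")
  items <- if (is.list(newdata) && is.null(newdata$image)) newdata
           else list(newdata)
  purrr::map_dfr(items, function(s) {
    y <- forward_cnn(object, as_cnn_input(s, object$input_dim))$y
    p <- (y + 1) / 2
    p <- if (sum(p) > 0) p / sum(p) else c(0.5, 0.5)
    if (p[2] == p[1]) {
      rlang::warn("tied class probabilities; resolving as benign")
    }
    tibble(label = if (p[2] > p[1]) "suspicious" else "benign",
           score = p[2], p_benign = p[1], p_suspicious = p[2])
  })
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Save / load a model
#'
#' The model file is JSON: an architecture header plus weight payloads
#' written as full-precision decimal strings, so a reloaded model predicts
#' bit-identically.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `save_cnn_model`: `path`, invisibly. `load_cnn_model`: the model.
#' @export
save_cnn_model <- function(model, path) {
  layers <- lapply(model$layers, function(l) {
    out <- l[setdiff(names(l), c("weights", "kernels"))]
    if (!is.null(l$weights))
      out$weights <- list(dim = dim(l$weights), data = fmt17(as.numeric(l$weights)))
    out
  })
  obj <- list(package = "dermoscan", format = 1L,
              input_dim = model$input_dim, n_outputs = model$n_outputs,
              trained = model$trained, seed = model$seed, layers = layers,
              history = if (!is.null(model$history)) list(
                epoch = model$history$epoch, loss = fmt17(model$history$loss)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  int <- function(x) as.integer(unlist(x))
  layers <- lapply(j$layers, function(l) {
    w <- l$weights
    l$weights <- NULL
    for (f in c("in_shape", "out_shape", "wdim"))
      if (!is.null(l[[f]])) l[[f]] <- int(l[[f]])
    for (f in c("mu")) if (!is.null(l[[f]])) l[[f]] <- num(l[[f]])
    for (f in c("filters", "size", "stride", "units", "n_in"))
      if (!is.null(l[[f]])) l[[f]] <- int(l[[f]])
    l$type <- as.character(l$type)
    l$trainable <- isTRUE(as.logical(l$trainable))
    if (!is.null(w)) {
      wd <- int(w$dim)
      wv <- as.numeric(unlist(w$data))
      l$weights <- if (length(wd) == 2) matrix(wv, wd[1], wd[2])
                   else array(wv, dim = wd)
    }
    l
  })
  model <- structure(list(input_dim = int(j$input_dim), layers = layers,
                          n_outputs = int(j$n_outputs),
                          trained = isTRUE(as.logical(j$trained)),
                          seed = int(j$seed), history = NULL),
                     class = "cnn_model")
  if (!is.null(j$history) && length(j$history))
    model$history <- tibble(epoch = int(j$history$epoch),
                            loss = num(j$history$loss))
  model
}
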