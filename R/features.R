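# Feature extraction: a frozen, deterministic mapping from preprocessed
# images to fixed-length vectors, plus the linear softmax head trained on
# top. Only the head is trainable; federation exchanges head parameters
# only (frozen-backbone contract).

#' Global average pooling
#'
#' Averages a feature map over its spatial positions, returning one value
#' per channel.
#'
#' @param feature_map H x W x C array.
#' @return Numeric vector of length C.
#' @export
global_average_pool <- function(feature_map) {
  apply(feature_map, 3, mean)
}

# 2x block-average downsample of a matrix (odd trailing row/col dropped).
downsample2 <- function(m) {
  n <- 2L * (nrow(m) %/% 2L); k <- 2L * (ncol(m) %/% 2L)
  m <- m[seq_len(n), seq_len(k), drop = FALSE]
  0.25 * (m[seq(1, n, 2), seq(1, k, 2)] + m[seq(2, n, 2), seq(1, k, 2)] +
          m[seq(1, n, 2), seq(2, k, 2)] + m[seq(2, n, 2), seq(2, k, 2)])
}

# Central-difference gradients; zero at the border (and everywhere for
# images narrower than 3 px).
grad_xy <- function(m) {
  n <- nrow(m); k <- ncol(m)
  gy <- matrix(0, n, k); gx <- matrix(0, n, k)
  if (n >= 3) gy[2:(n - 1), ] <- 0.5 * (m[3:n, ] - m[1:(n - 2), ])
  if (k >= 3) gx[, 2:(k - 1)] <- 0.5 * (m[, 3:k] - m[, 1:(k - 2)])
  list(gx = gx, gy = gy)
}

# Proportions over `nb` equal-width bins on [0, 1]; input assumed in [0, 1].
hist_props <- function(v, nb = 16L) {
  idx <- as.integer(v * nb) + 1L
  idx[idx > nb] <- nb
  tabulate(idx, nbins = nb) / length(v)
}

# Order-statistic quantile via partial sort (cheaper than quantile()).
quick_quantile <- function(v, p) {
  k <- max(1L, ceiling(p * length(v)))
  sort(v, partial = k)[k]
}

# The deterministic texture descriptor (d = 82): per-channel intensity
# histograms and moments, multiscale gradient-magnitude statistics,
# gradient-orientation histogram with coherence and entropy, band-pass
# (difference-of-Gaussians) statistics capturing beads/puncta, a
# high-frequency energy ratio, and connected-component statistics of the
# thresholded signal capturing network fragmentation.
texture_descriptor <- function(image) {
  f_hist <- unlist(lapply(1:3, function(ch) hist_props(image[, , ch])))
  f_mom <- unlist(lapply(1:3, function(ch) {
    v <- image[, , ch]
    c(mean(v), stats::sd(v))
  }))

  g <- image[, , 2]
  # fixed scale factor keeps the gradient/band-pass groups at O(1)
  # magnitude so a single learning rate suits the whole vector
  gscale <- 10
  grad_stats <- function(mag) {
    c(gscale * mean(mag), gscale * stats::sd(mag),
      gscale * quick_quantile(mag, 0.9), mean(mag > 0.06))
  }
  mag_of <- function(m) {
    gg <- grad_xy(m)
    sqrt(gg$gx^2 + gg$gy^2)
  }
  g2 <- downsample2(g); g4 <- downsample2(g2)
  f_grad <- c(grad_stats(mag_of(g)), grad_stats(mag_of(g2)),
              grad_stats(mag_of(g4)))

  # orientation statistics at half resolution (cheap, and filament
  # orientation is a coarse-scale property)
  gg2 <- grad_xy(g2)
  mag2 <- sqrt(gg2$gx^2 + gg2$gy^2)
  tot <- sum(mag2)
  if (tot > 0) {
    ang <- atan2(gg2$gy, gg2$gx) %% pi
    bin <- as.integer(ang / (pi / 8)) + 1L
    bin[bin > 8L] <- 8L
    ohist <- numeric(8)
    acc <- rowsum(as.vector(mag2), as.vector(bin))
    ohist[as.integer(rownames(acc))] <- acc[, 1]
    ohist <- ohist / tot
    coh <- sqrt(sum(mag2 * cos(2 * ang))^2 +
                  sum(mag2 * sin(2 * ang))^2) / tot
    pn <- ohist[ohist > 0]
    ent <- -sum(pn * log(pn)) / log(8)
  } else {
    ohist <- numeric(8); coh <- 0; ent <- 0
  }
  f_orient <- c(ohist, coh, ent)

  # band-pass (unsharp) response at half resolution: beads and puncta
  dog <- g2 - blur2d(g2, 1.5)
  adog <- abs(dog)
  f_dog <- c(gscale * stats::sd(dog), gscale * quick_quantile(adog, 0.95),
             gscale * mean(0.5 * (dog + adog)))
  f_hf <- f_grad[1] / (f_grad[1] + f_grad[9] + 1e-8)

  # network fragmentation: connected bright structures of the smoothed
  # half-resolution signal; noise specks are excluded by the size floor
  gs <- blur2d(g2, 0.8)
  # epsilon keeps float dust on constant regions below the threshold
  thr <- quick_quantile(gs, 0.80) + 1e-9
  bw <- matrix(as.numeric(gs > thr), nrow(gs))
  lab <- EBImage::bwlabel(bw)
  sizes <- tabulate(lab[lab > 0])
  big <- sizes[sizes >= 4]
  ncomp <- length(big)
  csize <- if (ncomp > 0) mean(big) else 0
  f_frag <- c(ncomp / (ncomp + 25), csize / (csize + 100))

  out <- c(f_hist, f_mom, f_grad, f_orient, f_dog, f_hf, f_frag)
  names(out) <- sprintf("feat_%03d", seq_along(out))
  out
}

#' Extract a feature vector from one image
#'
#' The default `texture_descriptor` backend is a deterministic handcrafted
#' descriptor (d = 82): per-channel 16-bin intensity histograms, per-channel
#' mean/SD, gradient-magnitude statistics at three scales,
#' gradient-orientation histogram with coherence and entropy,
#' difference-of-Gaussians band-pass statistics, a high-frequency energy
#' ratio, and connected-component statistics of the thresholded green
#' channel. It requires no downloaded weights and is the backend used by the
#' test-suite and benchmark. The `pretrained_cnn` backend stands for a
#' frozen ImageNet-pretrained convolutional backbone with global average
#' pooling (d = 1280); it needs pretrained weights on disk and is not
#' bundled.
#'
#' @param image 256 x 256 x 3 array in [0, 1] (any H x W >= 8 accepted for
#'   the texture backend).
#' @param backend `"texture_descriptor"` or `"pretrained_cnn"`.
#' @return Named numeric feature vector with attribute `backend_id`.
#' @export
extract_feature_vector <- function(image, backend = "texture_descriptor") {
  stopifnot_image(image)
  if (backend == "texture_descriptor") {
    v <- texture_descriptor(image)
  } else if (backend == "pretrained_cnn") {
    stop("pretrained_cnn backend requires ImageNet-pretrained weights, ",
         "which are not bundled; use backend = \"texture_descriptor\"",
         call. = FALSE)
  } else {
    stop("unknown backend: ", backend, call. = FALSE)
  }
  attr(v, "backend_id") <- backend
  v
}

#' Extract features for every image of a dataset
#'
#' Maps [extract_feature_vector()] over the `pixels` column and (by
#' default) applies the backbone's frozen per-feature scaling layer (see
#' [feature_scaling()]), which conditions the downstream head training.
#' Set `scale = FALSE` for the raw descriptor values.
#'
#' @param data A `col6_dataset` tibble with `pixels`.
#' @param backend Backend id, see [extract_feature_vector()].
#' @param scale Apply the frozen scaling constants?
#' @return The metadata columns of `data` plus a numeric matrix column
#'   `features` (one row per image).
#' @export
extract_features <- function(data, backend = "texture_descriptor",
                             scale = TRUE) {
  feats <- t(vapply(data$pixels, extract_feature_vector,
                    numeric(length(texture_descriptor(
                      array(0, c(8, 8, 3))))),
                    backend = backend))
  if (scale && backend == "texture_descriptor") {
    feats <- scale_feature_matrix(feats)
  }
  out <- data[, setdiff(names(data), "pixels"), drop = FALSE]
  out$features <- feats
  attr(out, "backend_id") <- backend
  tibble::as_tibble(out)
}

#' Model parameters of the linear softmax head
#'
#' @param d Feature dimension.
#' @param k Number of classes.
#' @param init `"zero"` or `"gaussian"` (SD 0.01, seeded).
#' @param seed Seed for Gaussian initialization.
#' @return A `model_params` object with `weights` (d x k) and `bias`
#'   (length k).
#' @export
model_params <- function(d, k = 4L, init = "zero", seed = 0L) {
  w <- switch(init,
              zero = matrix(0, d, k),
              gaussian = with_seed(seed,
                                   matrix(stats::rnorm(d * k, 0, 0.01), d,
                                          k)),
              stop("unknown init: ", init, call. = FALSE))
  structure(list(weights = w, bias = numeric(k)), class = "model_params")
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Class probabilities under a softmax head
#'
#' `softmax(t(weights) %*% f + bias)` for each feature row.
#'
#' @param params A `model_params` object.
#' @param features Numeric matrix (n x d) or a single vector of length d.
#' @return n x k matrix of probabilities; rows sum to 1.
#' @export
predict_probs <- function(params, features) {
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  if (ncol(features) != nrow(params$weights)) {
    stop("feature dimension ", ncol(features),
         " does not match head dimension ", nrow(params$weights),
         call. = FALSE)
  }
  z <- features %*% params$weights +
    matrix(params$bias, nrow(features), length(params$bias), byrow = TRUE)
  softmax_rows(z)
}

# Regularized loss and its analytic gradient. Loss = mean cross-entropy +
# lambda * ||W||^2 (bias unpenalized).
head_loss <- function(params, X, y, lambda) {
  p <- predict_probs(params, X)
  idx <- cbind(seq_len(nrow(X)), y)
  -mean(log(pmax(p[idx], 1e-300))) + lambda * sum(params$weights^2)
}

head_grad <- function(params, X, y, lambda) {
  n <- nrow(X)
  p <- predict_probs(params, X)
  Y <- matrix(0, n, ncol(p))
  Y[cbind(seq_len(n), y)] <- 1
  D <- (p - Y) / n
  list(weights = crossprod(X, D) + 2 * lambda * params$weights,
       bias = colSums(D))
}

#' Train the softmax head by gradient descent
#'
#' Minimizes mean softmax cross-entropy plus an L2 penalty on the weights
#' (`lambda * ||W||^2`, bias unpenalized) by gradient descent with a fixed
#' learning rate: full-batch when `batch_size` is `NULL` (the default; the
#' objective is then convex and the loss non-increasing for small enough
#' rates), or seeded mini-batch SGD otherwise. Deterministic given `seed`.
#'
#' @param X n x d feature matrix.
#' @param y Integer class indices in 1..k.
#' @param params0 Initial `model_params` (defines d and k).
#' @param epochs Number of passes (>= 0).
#' @param learning_rate Step size (>= 0; 0 is a degenerate no-op
#'   used by zero-step-size contracts).
#' @param lambda L2 penalty on the weights.
#' @param batch_size `NULL` for full-batch, else mini-batch size.
#' @param seed Seed for mini-batch shuffling.
#' @return A `col6_head` object: final `model_params` plus a per-epoch loss
#'   history.
#' @export
train_head <- function(X, y, params0, epochs = 20, learning_rate = 0.1,
                       lambda = 1e-3, batch_size = NULL, seed = 0L) {
  if (is.null(dim(X)) || nrow(X) == 0) {
    stop("empty training set", call. = FALSE)
  }
  stopifnot(length(y) == nrow(X), learning_rate >= 0, epochs >= 0)
  params <- params0
  losses <- numeric(epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (is.null(batch_size)) {
        g <- head_grad(params, X, y, lambda)
        params$weights <- params$weights - learning_rate * g$weights
        params$bias <- params$bias - learning_rate * g$bias
      } else {
        ord <- sample.int(nrow(X))
        for (start in seq(1, nrow(X), by = batch_size)) {
          bi <- ord[start:min(start + batch_size - 1, nrow(X))]
          g <- head_grad(params, X[bi, , drop = FALSE], y[bi], lambda)
          params$weights <- params$weights - learning_rate * g$weights
          params$bias <- params$bias - learning_rate * g$bias
        }
      }
      losses[ep] <- head_loss(params, X, y, lambda)
    }
  })
  structure(list(weights = params$weights, bias = params$bias,
                 history = tibble::tibble(epoch = seq_len(epochs),
                                          loss = losses),
                 hyper = list(epochs = epochs,
                              learning_rate = learning_rate,
                              lambda = lambda, batch_size = batch_size,
                              seed = seed)),
            class = c("col6_head", "model_params"))
}

#' Fit a head on an extracted-features tibble
#'
#' Tidy wrapper around [train_head()]: takes the output of
#' [extract_features()] and trains on its `features` and `class_index`
#' columns.
#'
#' @param data Tibble with `features` matrix column and `class_index`.
#' @param k Number of classes (default 4).
#' @inheritParams train_head
#' @param ... Passed to [train_head()].
#' @return A `col6_head`.
#' @export
fit_head <- function(data, k = 4L, epochs = 100, learning_rate = 0.5,
                     lambda = 1e-3, ...) {
  fit <- train_head(data$features, data$class_index,
                    model_params(ncol(data$features), k),
                    epochs = epochs, learning_rate = learning_rate,
                    lambda = lambda, ...)
  fit$class_levels <- class_labels()[seq_len(k)]
  fit
}

#' @export
predict.col6_head <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  X <- if (is.matrix(newdata)) newdata else newdata$features
  p <- predict_probs(object, X)
  if (type == "prob") {
    colnames(p) <- object$class_levels %||% paste0("class", seq_len(ncol(p)))
    return(tibble::as_tibble(p))
  }
  max.col(p, ties.method = "first")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.col6_head <- function(x, ...) {
  k <- length(x$bias)
  cls <- x$class_levels %||% paste0("class", seq_len(k))
  dplyr::bind_rows(
    tibble::tibble(term = "bias", class = cls, estimate = x$bias),
    tidyr::pivot_longer(
      tibble::as_tibble(stats::setNames(as.data.frame(x$weights), cls)) |>
        dplyr::mutate(term = rownames(x$weights) %||%
                        sprintf("feat_%03d", seq_len(nrow(x$weights)))),
      cols = -"term", names_to = "class", values_to = "estimate")
  )
}

#' @exportS3Method generics::glance
glance.col6_head <- function(x, ...) {
  tibble::tibble(
    d = nrow(x$weights), k = length(x$bias),
    epochs = x$hyper$epochs,
    learning_rate = x$hyper$learning_rate,
    lambda = x$hyper$lambda,
    final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)]
                 else NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
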