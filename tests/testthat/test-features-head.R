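test_that("the texture descriptor is deterministic and zeros out on flat input", {
  img <- smooth_image(64)
  expect_identical(extract_feature_vector(img), extract_feature_vector(img))

  flat <- array(0.3, c(64, 64, 3))
  v <- extract_feature_vector(flat)
  # gradient-magnitude features of a flat image are exactly zero; the
  # remaining structure features are zero up to blur round-off
  expect_true(all(v[55:66] == 0))
  expect_lt(max(abs(v[67:82])), 1e-9)

  expect_error(extract_feature_vector(img, backend = "vgg"), "unknown")
  expect_error(extract_feature_vector(img, backend = "pretrained_cnn"),
               "texture_descriptor")
})

test_that("global average pooling of a uniform feature map is the channel value", {
  fm <- array(rep(c(1.5, -2, 0.25), each = 12), c(3, 4, 3))
  expect_equal(global_average_pool(fm), c(1.5, -2, 0.25))
})

test_that("softmax head probabilities are normalized and order-preserving", {
  p0 <- model_params(5, 4)
  f <- runif(5)
  expect_equal(as.numeric(predict_probs(p0, f)), rep(0.25, 4))

  set.seed(1)
  params <- model_params(5, 4, init = "gaussian", seed = 2)
  X <- matrix(rnorm(50 * 5), 50)
  probs <- predict_probs(params, X)
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  logits <- X %*% params$weights
  expect_equal(max.col(probs), max.col(logits))

  expect_error(predict_probs(params, matrix(0, 2, 7)), "dimension")
})

test_that("gradient descent solves a separable toy problem and matches a finite-difference oracle", {
  X <- rbind(matrix(rnorm(8, -2, 0.3), 4), matrix(rnorm(8, 2, 0.3), 4))
  y <- rep(1:2, each = 4)
  fit <- train_head(X, y, model_params(2, 2), epochs = 400,
                    learning_rate = 0.5, lambda = 1e-4)
  expect_equal(max.col(predict_probs(fit, X)), y)

  # one full-batch step against a central finite-difference gradient
  set.seed(9)
  X2 <- matrix(rnorm(12 * 3), 12)
  y2 <- sample(1:3, 12, replace = TRUE)
  p0 <- model_params(3, 3, init = "gaussian", seed = 4)
  lam <- 1e-2
  eta <- 0.2
  stepped <- train_head(X2, y2, p0, epochs = 1, learning_rate = eta,
                        lambda = lam)
  loss_at <- function(w, b) {
    col6fl:::head_loss(structure(list(weights = w, bias = b),
                                 class = "model_params"), X2, y2, lam)
  }
  h <- 1e-5
  gw <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    wp <- p0$weights; wp[i, j] <- wp[i, j] + h
    wm <- p0$weights; wm[i, j] <- wm[i, j] - h
    gw[i, j] <- (loss_at(wp, p0$bias) - loss_at(wm, p0$bias)) / (2 * h)
  }
  gb <- numeric(3)
  for (j in 1:3) {
    bp <- p0$bias; bp[j] <- bp[j] + h
    bm <- p0$bias; bm[j] <- bm[j] - h
    gb[j] <- (loss_at(p0$weights, bp) - loss_at(p0$weights, bm)) / (2 * h)
  }
  expect_lt(max(abs(stepped$weights - (p0$weights - eta * gw))), 1e-4)
  expect_lt(max(abs(stepped$bias - (p0$bias - eta * gb))), 1e-4)

  expect_error(train_head(X2[0, , drop = FALSE], integer(0),
                          model_params(3, 3)), "empty")
})

test_that("heavy regularization drives the weights to zero while the bias tracks priors", {
  set.seed(11)
  X <- matrix(rnorm(60 * 4), 60)
  y <- sample(1:3, 60, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  fit <- train_head(X, y, model_params(4, 3), epochs = 2000,
                    learning_rate = 0.005, lambda = 50)
  expect_lt(max(abs(fit$weights)), 1e-3)
  pri <- predict_probs(fit, matrix(0, 1, 4))
  expect_equal(order(pri), order(tabulate(y, 3)))
})

test_that("full-batch loss is non-increasing on the convex objective", {
  for (s in 1:3) {
    set.seed(s)
    X <- matrix(rnorm(40 * 6), 40)
    y <- sample(1:4, 40, replace = TRUE)
    fit <- train_head(X, y, model_params(6, 4), epochs = 60,
                      learning_rate = 0.05, lambda = 1e-3)
    expect_true(all(diff(fit$history$loss) <= 1e-12))
  }
})

test_that("fit_head works on extracted-feature tibbles and tidies", {
  d <- generate_federated_dataset(tiny_profiles(), seed = 8)
  d$pixels <- purrr::map(d$pixels, resize_normalize)
  f <- extract_features(d)
  expect_equal(ncol(f$features), 82)
  fit <- fit_head(f, epochs = 50, learning_rate = 0.3)
  expect_s3_class(fit, "col6_head")
  preds <- predict(fit, f)
  expect_true(all(preds %in% 1:4))
  probs <- predict(fit, f, type = "prob")
  expect_equal(names(probs), class_labels())
  td <- generics::tidy(fit)
  expect_setequal(unique(td$class), class_labels())
  expect_equal(nrow(td), (82 + 1) * 4)
  gl <- generics::glance(fit)
  expect_equal(gl$d, 82)
  expect_equal(gl$epochs, 50)
})
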