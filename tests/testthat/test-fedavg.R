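# Synthetic feature nodes for federation tests: Gaussian class clusters with
# a per-node mean shift, mimicking two sites with covariate shift.
synth_nodes <- function(n = c(60, 20), d = 6, k = 3, seed = 1) {
  set.seed(seed)
  mk <- function(n_i, shift, sid) {
    y <- sample(1:k, n_i, replace = TRUE)
    X <- matrix(rnorm(n_i * d, sd = 0.6), n_i) + shift +
      outer(y, rep(1, d)) * 0.8
    tibble::tibble(site_id = sid, class_index = y, features = X)
  }
  list(make_node(mk(n[1], 0, "big")), make_node(mk(n[2], 0.5, "small")))
}

test_that("local updates are seeded, initialized from the broadcast, and no-ops at zero step", {
  nodes <- synth_nodes()
  cfg <- fedavg_config(rounds = 3, learning_rate = 0.2)
  p0 <- model_params(6, 3, init = "gaussian", seed = 3)

  u1 <- local_update(nodes[[1]], p0, cfg, round = 1)
  u2 <- local_update(nodes[[1]], p0, cfg, round = 1)
  expect_identical(u1, u2)
  expect_equal(u1$n, nodes[[1]]$n)

  cfg0 <- cfg
  cfg0$learning_rate <- 0
  frozen <- local_update(nodes[[1]], p0, cfg0)
  expect_equal(frozen$params$weights, p0$weights)
  expect_equal(frozen$params$bias, p0$bias)

  # one full-batch epoch is one analytic gradient step
  one <- local_update(nodes[[1]], p0, fedavg_config(learning_rate = 0.3))
  g <- col6fl:::head_grad(p0, nodes[[1]]$X, nodes[[1]]$y, 1e-3)
  expect_lt(max(abs(one$params$weights - (p0$weights - 0.3 * g$weights))),
            1e-6)
})

test_that("FedAvg aggregation is the weighted mean with the documented weightings", {
  p <- function(v) structure(list(weights = matrix(v, 1, 1), bias = 0),
                             class = "model_params")
  single <- fedavg_aggregate(list(list(params = p(2.5), n = 7)))
  expect_equal(single$weights[1, 1], 2.5)

  same <- fedavg_aggregate(list(list(params = p(1.25), n = 3),
                                list(params = p(1.25), n = 9)))
  expect_equal(same$weights[1, 1], 1.25)

  two <- fedavg_aggregate(list(list(params = p(0), n = 1),
                               list(params = p(4), n = 3)))
  expect_equal(two$weights[1, 1], 3)  # (1*0 + 3*4) / 4

  unif <- fedavg_aggregate(list(list(params = p(0), n = 1),
                                list(params = p(4), n = 3)),
                           weighting = "uniform")
  expect_equal(unif$weights[1, 1], 2)

  expect_error(fedavg_aggregate(list(
    list(params = structure(list(weights = matrix(0, 2, 2), bias = 0),
                            class = "model_params"), n = 1),
    list(params = p(1), n = 1))), "shapes")
  expect_error(fedavg_aggregate(list(list(params = p(1), n = 0),
                                     list(params = p(2), n = 0))), "zero")
})

test_that("aggregation is affine-equivariant", {
  set.seed(5)
  mk <- function() {
    structure(list(weights = matrix(rnorm(6), 2), bias = rnorm(3)),
              class = "model_params")
  }
  th <- list(mk(), mk(), mk())
  n <- c(4, 10, 2)
  a <- 1.7; b <- -0.4
  shifted <- purrr::map(th, function(p) {
    structure(list(weights = a * p$weights + b, bias = a * p$bias + b),
              class = "model_params")
  })
  agg <- fedavg_aggregate(purrr::map2(th, n, ~ list(params = .x, n = .y)))
  agg_shift <- fedavg_aggregate(purrr::map2(shifted, n,
                                            ~ list(params = .x, n = .y)))
  expect_equal(agg_shift$weights, a * agg$weights + b)
  expect_equal(agg_shift$bias, a * agg$bias + b)
})

test_that("federated training reduces to its degenerate cases", {
  nodes <- synth_nodes()
  p0 <- model_params(6, 3, init = "gaussian", seed = 6)

  r0 <- run_federated(nodes, fedavg_config(rounds = 0), p0)
  expect_equal(r0$weights, p0$weights)
  expect_equal(nrow(r0$history), 0)

  cfg <- fedavg_config(rounds = 5, learning_rate = 0.2)
  solo_fed <- run_federated(nodes[1], cfg, p0)
  seq_params <- p0
  for (r in 1:5) {
    seq_params <- local_update(nodes[[1]], seq_params, cfg, round = r)$params
  }
  expect_equal(solo_fed$weights, seq_params$weights)

  single <- run_single_node(nodes[[1]], cfg, p0)
  expect_equal(single$weights, solo_fed$weights, tolerance = 1e-12)
  expect_equal(nrow(solo_fed$history), 5)
})

test_that("with one full-batch local epoch FedAvg equals pooled centralized descent", {
  nodes <- synth_nodes(n = c(80, 25), seed = 7)
  cfg <- fedavg_config(rounds = 20, learning_rate = 0.1, lambda = 1e-3)
  p0 <- model_params(6, 3)

  fed <- run_federated(nodes, cfg, p0)

  Xp <- rbind(nodes[[1]]$X, nodes[[2]]$X)
  yp <- c(nodes[[1]]$y, nodes[[2]]$y)
  pooled <- train_head(Xp, yp, p0, epochs = 20, learning_rate = 0.1,
                       lambda = 1e-3)
  expect_lt(max(abs(fed$weights - pooled$weights),
                abs(fed$bias - pooled$bias)), 1e-6)
})

test_that("the node API never exposes raw data to the aggregator", {
  nodes <- synth_nodes()
  cfg <- fedavg_config(rounds = 2)
  upd <- local_update(nodes[[1]], model_params(6, 3), cfg)
  expect_named(upd, c("params", "n"))
  expect_named(upd$params, c("weights", "bias"))
  # a federation built from update objects alone must succeed
  expect_s3_class(fedavg_aggregate(list(upd, upd))$weights, NA)
})
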