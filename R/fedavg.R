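# Horizontal federated training with FedAvg aggregation.
#
# Privacy boundary (structural): no function in this file accepts raw
# features from more than one node. Nodes exchange only head parameters and
# sample counts with the aggregator; the pooled-centralized baseline, which
# deliberately breaks that boundary as an upper reference, lives in the
# orchestration layer instead.

#' Create a federation node
#'
#' Wraps one site's training features and labels as a node. Only head
#' parameters and the sample count ever leave a node during federation.
#'
#' @param data Extracted-features tibble (from [extract_features()]),
#'   training rows of a single site.
#' @param site_id Node id; defaults to the (unique) `site_id` of `data`.
#' @return A `col6_node` object with fields `site_id`, `X`, `y`, `n`.
#' @export
make_node <- function(data, site_id = NULL) {
  sid <- site_id %||% unique(data$site_id)
  if (length(sid) != 1) {
    stop("a node must hold data from exactly one site", call. = FALSE)
  }
  if (nrow(data) == 0) stop("empty node: ", sid, call. = FALSE)
  structure(list(site_id = sid, X = data$features, y = data$class_index,
                 n = nrow(data)),
            class = "col6_node")
}

#' @export
print.col6_node <- function(x, ...) {
  cat("<col6_node> ", x$site_id, ": n = ", x$n, ", d = ", ncol(x$X), "\n",
      sep = "")
  invisible(x)
}

#' FedAvg training configuration
#'
#' Defaults (`rounds = 20`, one full-batch local epoch, learning rate 0.1,
#' lambda 1e-3, sample-count weighting) are the regime in which one
#' federated round is mathematically identical to one full-batch gradient
#' step on the pooled data, which makes the implementation directly
#' verifiable against a centralized oracle. The benchmark experiment uses a
#' longer schedule (see [experiment_config()]).
#'
#' @param rounds Number of federated rounds R (>= 0).
#' @param local_epochs Local epochs E per round (>= 1).
#' @param learning_rate Step size (> 0).
#' @param lambda L2 penalty on head weights.
#' @param batch_size `NULL` for full-batch local training.
#' @param weighting `"sample_count"` (weights n_k / sum n) or `"uniform"`.
#' @param seed Seed for local mini-batch shuffling.
#' @return A `fedavg_config` object.
#' @export
fedavg_config <- function(rounds = 20L, local_epochs = 1L,
                          learning_rate = 0.1, lambda = 1e-3,
                          batch_size = NULL,
                          weighting = c("sample_count", "uniform"),
                          seed = 0L) {
  if (rounds < 0) stop("rounds must be >= 0", call. = FALSE)
  if (local_epochs < 1) stop("local_epochs must be >= 1", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  structure(list(rounds = as.integer(rounds),
                 local_epochs = as.integer(local_epochs),
                 learning_rate = learning_rate, lambda = lambda,
                 batch_size = batch_size,
                 weighting = match.arg(weighting),
                 seed = as.integer(seed)),
            class = "fedavg_config")
}

#' One local update
#'
#' Initializes from the broadcast global parameters and runs
#' [train_head()] for `local_epochs` on the node's private data.
#'
#' @param node A [make_node()] object.
#' @param global_params `model_params` broadcast by the aggregator.
#' @param cfg A [fedavg_config()].
#' @param round Round index, folded into the local shuffling seed.
#' @return List with elements `params` (updated `model_params`) and `n`
#'   (local sample count).
#' @export
local_update <- function(node, global_params, cfg, round = 1L) {
  if (!inherits(node, "col6_node")) stop("not a node", call. = FALSE)
  fit <- train_head(node$X, node$y, global_params,
                    epochs = cfg$local_epochs,
                    learning_rate = cfg$learning_rate,
                    lambda = cfg$lambda, batch_size = cfg$batch_size,
                    seed = derive_seed(cfg$seed, round))
  list(params = structure(list(weights = fit$weights, bias = fit$bias),
                          class = "model_params"),
       n = node$n)
}

#' FedAvg aggregation
#'
#' Element-wise weighted mean of the submitted parameter updates, with
#' weights `n_k / sum(n)` (`sample_count`) or `1 / M` (`uniform`).
#'
#' @param updates List of `list(params, n)` as returned by
#'   [local_update()].
#' @param weighting `"sample_count"` or `"uniform"`.
#' @return Aggregated `model_params`.
#' @export
fedavg_aggregate <- function(updates,
                             weighting = c("sample_count", "uniform")) {
  weighting <- match.arg(weighting)
  if (length(updates) == 0) stop("no updates to aggregate", call. = FALSE)
  dims <- lapply(updates, function(u) dim(u$params$weights))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    stop("parameter shapes differ across updates", call. = FALSE)
  }
  n <- vapply(updates, `[[`, numeric(1), "n")
  w <- if (weighting == "sample_count") {
    if (sum(n) == 0) stop("total sample count is zero", call. = FALSE)
    n / sum(n)
  } else {
    rep(1 / length(updates), length(updates))
  }
  agg <- list(weights = 0 * updates[[1]]$params$weights,
              bias = 0 * updates[[1]]$params$bias)
  for (i in seq_along(updates)) {
    agg$weights <- agg$weights + w[i] * updates[[i]]$params$weights
    agg$bias <- agg$bias + w[i] * updates[[i]]$params$bias
  }
  structure(agg, class = "model_params")
}

#' Run federated training
#'
#' For each of `cfg$rounds`: broadcast the global parameters, collect a
#' [local_update()] from every node (full participation), and
#' [fedavg_aggregate()] the results. With one full-batch local epoch and
#' sample-count weighting, each round equals one full-batch gradient step on
#' the pooled data.
#'
#' @param nodes List of [make_node()] objects.
#' @param cfg A [fedavg_config()].
#' @param params0 Initial global `model_params`.
#' @return A `col6_fedavg` object: final `model_params` plus a per-round
#'   `history` tibble (weighted global loss, per-node local losses, max abs
#'   parameter change).
#' @export
run_federated <- function(nodes, cfg, params0) {
  if (length(nodes) == 0) stop("need at least one node", call. = FALSE)
  params <- params0
  hist <- vector("list", cfg$rounds)
  for (r in seq_len(cfg$rounds)) {
    updates <- lapply(nodes, local_update, global_params = params,
                      cfg = cfg, round = r)
    new_params <- fedavg_aggregate(updates, cfg$weighting)
    delta <- max(abs(new_params$weights - params$weights),
                 abs(new_params$bias - params$bias))
    params <- new_params
    local_loss <- vapply(nodes, function(nd) {
      head_loss(params, nd$X, nd$y, cfg$lambda)
    }, numeric(1))
    n <- vapply(nodes, `[[`, numeric(1), "n")
    hist[[r]] <- tibble::tibble(
      round = r,
      global_loss = sum(local_loss * n / sum(n)),
      site_id = vapply(nodes, `[[`, "", "site_id"),
      local_loss = local_loss,
      param_delta = delta)
  }
  structure(list(weights = params$weights, bias = params$bias,
                 history = dplyr::bind_rows(hist), cfg = cfg,
                 class_levels = class_labels()[seq_along(params$bias)]),
            class = c("col6_fedavg", "col6_head", "model_params"))
}

#' Single-node baseline
#'
#' Trains on one node's data alone with the same total optimization budget
#' as the federated run (`rounds * local_epochs` epochs) and the same seed
#' discipline, so single-node-versus-federated comparisons are not
#' confounded by training length.
#'
#' @inheritParams run_federated
#' @param node A single [make_node()] object.
#' @return A `col6_head`.
#' @export
run_single_node <- function(node, cfg, params0) {
  fit <- train_head(node$X, node$y, params0,
                    epochs = cfg$rounds * cfg$local_epochs,
                    learning_rate = cfg$learning_rate, lambda = cfg$lambda,
                    batch_size = cfg$batch_size,
                    seed = derive_seed(cfg$seed, 1L))
  fit$class_levels <- class_labels()[seq_along(fit$bias)]
  fit
}

#' @exportS3Method generics::tidy
tidy.col6_fedavg <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.col6_fedavg <- function(x, ...) {
  tibble::tibble(
    rounds = x$cfg$rounds, local_epochs = x$cfg$local_epochs,
    learning_rate = x$cfg$learning_rate, lambda = x$cfg$lambda,
    weighting = x$cfg$weighting,
    final_global_loss = if (nrow(x$history)) {
      x$history$global_loss[nrow(x$history)]
    } else NA_real_
  )
}
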