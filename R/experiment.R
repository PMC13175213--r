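# End-to-end experiment orchestration: generate data, split at the patient
# level, augment training partitions only, extract features, train the
# single-node / federated / pooled arms under a matched epoch budget, and
# evaluate all arms on the shared hold-out set over repeated seeded trials.

#' Experiment configuration
#'
#' Defaults reproduce the benchmark protocol: the two-site scenario with
#' the published image distribution (300 vs 31), the standard augmentation
#' pipeline on training data only, the deterministic texture backend, a
#' hold-out of 24 images (20 large-site, 4 small-site), 10 trials, and a
#' federated schedule of 300 rounds with one full-batch local epoch
#' (learning rate 0.5, lambda 1e-4, sample-count weighting). Single-node
#' and pooled arms receive the same total number of optimization passes
#' (`rounds * local_epochs`), so comparisons are not confounded by training
#' length.
#'
#' @param profiles List of [site_profile()]s.
#' @param augmentation An [augmentation_config()].
#' @param backend Feature backend id.
#' @param fed A [fedavg_config()]; its seed is re-derived per trial.
#' @param n_trials Number of repeated trials (>= 1).
#' @param test_counts Named vector site -> hold-out image count.
#' @param seed Root seed; the whole comparison is a pure function of
#'   (config, seed).
#' @param include_pooled Add the pooled-centralized upper-reference arm?
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(profiles = default_site_profiles(),
                              augmentation = augmentation_config(),
                              backend = "texture_descriptor",
                              fed = fedavg_config(rounds = 300L,
                                                  local_epochs = 1L,
                                                  learning_rate = 0.5,
                                                  lambda = 1e-4),
                              n_trials = 10L,
                              test_counts = c(NIH = 20L, UCL = 4L),
                              seed = 1L,
                              include_pooled = TRUE) {
  stopifnot(n_trials >= 1)
  sids <- vapply(profiles, `[[`, "", "site_id")
  if (!all(names(test_counts) %in% sids)) {
    stop("test_counts references unknown sites: ",
         paste(setdiff(names(test_counts), sids), collapse = ", "),
         call. = FALSE)
  }
  structure(list(profiles = profiles, augmentation = augmentation,
                 backend = backend, fed = fed,
                 n_trials = as.integer(n_trials),
                 test_counts = test_counts, seed = as.integer(seed),
                 include_pooled = isTRUE(include_pooled)),
            class = "experiment_config")
}

# Resize/normalize pixels in place, then stream augmentation variants of
# the training rows of one site straight into feature rows, so the 5x
# augmented images are never all held in memory.
augmented_feature_rows <- function(train_rows, aug_cfg, backend) {
  d <- length(extract_feature_vector(array(0, c(8, 8, 3)), backend))
  n_var <- 1L + length(aug_cfg$rotation_angles) +
    as.integer(aug_cfg$apply_hflip) + length(aug_cfg$brightness_factors)
  feats <- matrix(0, nrow(train_rows) * n_var, d)
  for (i in seq_len(nrow(train_rows))) {
    vars <- augment_variants(train_rows$pixels[[i]], aug_cfg)
    for (j in seq_along(vars)) {
      feats[(i - 1L) * n_var + j, ] <-
        extract_feature_vector(vars[[j]], backend)
    }
  }
  if (backend == "texture_descriptor") {
    feats <- scale_feature_matrix(feats)
  }
  meta <- train_rows[rep(seq_len(nrow(train_rows)), each = n_var),
                     setdiff(names(train_rows), "pixels"), drop = FALSE]
  out <- tibble::as_tibble(meta)
  out$features <- feats
  out
}

eval_arm <- function(fit, test_feats) {
  pred <- predict(fit, test_feats)
  list(
    multi = evaluation_report(test_feats$class_index, pred, k = 4L),
    binary = evaluation_report(binarize_labels(test_feats$class_index) + 1L,
                               binarize_labels(pred) + 1L, k = 2L,
                               labels = c("control", "pathogenic"))
  )
}

run_trial <- function(cfg, trial) {
  tseed <- derive_seed(cfg$seed, 1000 + trial)
  data <- generate_federated_dataset(cfg$profiles, seed = tseed)
  data <- split_patient_level(data, cfg$test_counts,
                              seed = derive_seed(tseed, 1))
  data$pixels <- purrr::map(data$pixels, resize_normalize,
                            size = cfg$augmentation$target_size)

  test_feats <- extract_features(partition_images(data, "test"),
                                 backend = cfg$backend)
  train <- partition_images(data, "train")
  rm(data)

  site_ids <- vapply(cfg$profiles, `[[`, "", "site_id")
  site_feats <- lapply(site_ids, function(sid) {
    augmented_feature_rows(train[train$site_id == sid, , drop = FALSE],
                           cfg$augmentation, cfg$backend)
  })
  names(site_feats) <- site_ids
  rm(train)

  nodes <- lapply(site_feats, make_node)
  d <- ncol(nodes[[1]]$X)
  params0 <- model_params(d, 4L)
  fedcfg <- cfg$fed
  fedcfg$seed <- derive_seed(tseed, 2)

  fits <- list()
  for (sid in site_ids) {
    fits[[paste0(sid, "-only")]] <- run_single_node(nodes[[sid]], fedcfg,
                                                    params0)
  }
  fits[["federated"]] <- run_federated(nodes, fedcfg, params0)
  if (cfg$include_pooled) {
    pooled <- dplyr::bind_rows(site_feats)
    fits[["pooled"]] <- fit_head(pooled, k = 4L,
                                 epochs = fedcfg$rounds * fedcfg$local_epochs,
                                 learning_rate = fedcfg$learning_rate,
                                 lambda = fedcfg$lambda,
                                 batch_size = fedcfg$batch_size,
                                 seed = derive_seed(tseed, 3))
  }
  lapply(fits, eval_arm, test_feats = test_feats)
}

#' Run the single-node-versus-federated comparison
#'
#' For each trial (with a per-trial derived seed covering rendering, the
#' patient-level split, augmentation and head training): generate the
#' dataset, split, augment the training partitions only, extract features,
#' train every arm under a matched epoch budget, and evaluate all arms —
#' four-class and binarized — on the trial's shared hold-out set. The
#' entire comparison is a deterministic function of (config, seed).
#'
#' @param cfg An [experiment_config()].
#' @param progress Print a line per trial?
#' @return A `col6_comparison` object with per-trial metrics, per-arm
#'   mean/SD summaries, and per-arm confusion matrices summed over trials.
#' @export
run_comparison <- function(cfg = experiment_config(), progress = FALSE) {
  trial_rows <- list()
  confusions <- list()
  for (t in seq_len(cfg$n_trials)) {
    res <- run_trial(cfg, t)
    for (arm in names(res)) {
      r <- res[[arm]]
      trial_rows[[length(trial_rows) + 1L]] <- tibble::tibble(
        trial = t, arm = arm,
        macro_f1 = r$multi$macro_f1, accuracy = r$multi$accuracy,
        bin_macro_f1 = r$binary$macro_f1, bin_accuracy = r$binary$accuracy)
      confusions[[arm]] <- if (is.null(confusions[[arm]])) {
        unclass(r$multi$confusion)
      } else {
        confusions[[arm]] + unclass(r$multi$confusion)
      }
    }
    if (progress) {
      message("trial ", t, "/", cfg$n_trials, " done")
    }
    gc(FALSE)
  }
  trials <- dplyr::bind_rows(trial_rows)
  summary <- trials |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      mean_f1 = mean(.data$macro_f1),
      std_f1 = stats::sd(.data$macro_f1),
      mean_accuracy = mean(.data$accuracy),
      std_accuracy = stats::sd(.data$accuracy),
      mean_bin_f1 = mean(.data$bin_macro_f1),
      std_bin_f1 = stats::sd(.data$bin_macro_f1),
      mean_bin_accuracy = mean(.data$bin_accuracy),
      std_bin_accuracy = stats::sd(.data$bin_accuracy),
      .groups = "drop")
  structure(list(trials = trials, summary = summary,
                 confusion = confusions,
                 meta = list(seed = cfg$seed, n_trials = cfg$n_trials,
                             backend = cfg$backend,
                             rounds = cfg$fed$rounds,
                             local_epochs = cfg$fed$local_epochs)),
            class = "col6_comparison")
}

#' @export
print.col6_comparison <- function(x, ...) {
  cat("<col6_comparison> ", x$meta$n_trials, " trials, seed ", x$meta$seed,
      "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.col6_comparison <- function(x, ...) x$summary

#' @exportS3Method generics::glance
glance.col6_comparison <- function(x, ...) {
  tibble::as_tibble(x$meta)
}

#' Federated-versus-single-node gains
#'
#' Absolute and relative improvements of the federated arm over each
#' single-node arm, computed from a per-arm summary table (either a
#' [run_comparison()] summary or any table with `arm`, `mean_f1`,
#' `mean_accuracy` columns, such as the published reference results).
#'
#' @param summary Per-arm summary tibble.
#' @param federated_arm Name of the federated arm in `summary`.
#' @return Tibble with one row per non-federated arm: absolute and relative
#'   (percent) F1 and accuracy gains of the federated model.
#' @export
federation_gains <- function(summary, federated_arm = "federated") {
  fed <- summary[summary$arm == federated_arm, , drop = FALSE]
  if (nrow(fed) != 1) stop("federated arm not found", call. = FALSE)
  base <- summary[summary$arm != federated_arm, , drop = FALSE]
  tibble::tibble(
    arm = base$arm,
    delta_f1 = fed$mean_f1 - base$mean_f1,
    rel_f1_pct = 100 * (fed$mean_f1 - base$mean_f1) / base$mean_f1,
    delta_accuracy = fed$mean_accuracy - base$mean_accuracy,
    rel_accuracy_pct = 100 * (fed$mean_accuracy - base$mean_accuracy) /
      base$mean_accuracy)
}

#' Published reference results
#'
#' The per-arm mean/SD summary reported by the original two-site federated
#' evaluation on the private institutional images, shipped as a reference
#' table. These numbers are inputs for arithmetic (e.g.
#' [federation_gains()]), not outputs of this package: the private images
#' are unavailable, so they cannot be recomputed here.
#'
#' @return Tibble with columns `arm`, `mean_f1`, `std_f1`,
#'   `mean_accuracy`, `std_accuracy`.
#' @export
published_reference <- function() {
  path <- system.file("extdata", "published_reference_results.csv",
                      package = "col6fl", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a comparison report to disk
#'
#' Writes `comparison.json` (full precision), `comparison.csv` (one row per
#' arm, three decimals), one `confusion_<arm>.csv` per arm, and a
#' deterministic `run.log`. [read_report()] restores the report losslessly.
#'
#' @param report A `col6_comparison`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create ", out_dir, call. = FALSE)
  jsonlite::write_json(
    list(meta = report$meta,
         trials = report$trials,
         summary = report$summary,
         confusion = report$confusion),
    file.path(out_dir, "comparison.json"),
    auto_unbox = TRUE, digits = NA)
  csv <- report$summary |>
    dplyr::mutate(dplyr::across(dplyr::where(is.double), ~ round(.x, 3)))
  utils::write.csv(csv, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  for (arm in names(report$confusion)) {
    utils::write.csv(as.data.frame(report$confusion[[arm]]),
                     file.path(out_dir, paste0("confusion_",
                                               gsub("[^A-Za-z0-9]", "_",
                                                    arm), ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  writeLines(c("col6fl comparison run",
               paste0("seed: ", report$meta$seed),
               paste0("n_trials: ", report$meta$n_trials),
               paste0("backend: ", report$meta$backend),
               paste0("rounds: ", report$meta$rounds),
               paste0("arms: ", paste(sort(unique(report$trials$arm)),
                                      collapse = ", "))),
             file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @rdname write_report
#' @param out_dir Directory previously written by [write_report()].
#' @export
read_report <- function(out_dir) {
  j <- jsonlite::read_json(file.path(out_dir, "comparison.json"),
                           simplifyVector = TRUE)
  conf <- lapply(j$confusion, function(m) {
    m <- as.matrix(m)
    storage.mode(m) <- "integer"
    dimnames(m) <- list(true = class_labels(), pred = class_labels())
    m
  })
  structure(list(trials = tibble::as_tibble(j$trials),
                 summary = tibble::as_tibble(j$summary),
                 confusion = conf,
                 meta = j$meta),
            class = "col6_comparison")
}
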