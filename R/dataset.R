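# Dataset assembly: patients, image counts, rendering, patient-level splits.
#
# A dataset is a tibble with one row per image: image_id, site_id,
# patient_id, class, class_index and a `pixels` list-column of H x W x 3
# arrays. The per-image random streams are derived from the root seed and a
# deterministic counter (site order x class order x patient x image), so any
# image can be re-rendered independently of the others.

# Split n_img images over n_pat patients: sizes drawn uniformly from the
# configured range, the last patient absorbs the rounding; a fix-up pass
# keeps every patient at >= 1 image. Must be called inside with_seed().
patient_image_sizes <- function(n_img, n_pat, range = c(2L, 6L)) {
  if (n_pat == 0L) return(integer(0))
  if (n_img < n_pat) stop("fewer images than patients", call. = FALSE)
  sizes <- sample(seq(range[1], range[2]), n_pat, replace = TRUE)
  sizes[n_pat] <- sizes[n_pat] + (n_img - sum(sizes))
  while (any(sizes < 1L)) {
    i <- which.min(sizes); j <- which.max(sizes)
    sizes[i] <- sizes[i] + 1L
    sizes[j] <- sizes[j] - 1L
  }
  stopifnot(sum(sizes) == n_img)
  as.integer(sizes)
}

#' Generate the synthetic two-site federated dataset
#'
#' Assigns every patient one site and one class, distributes images over
#' patients (uniform draw from each profile's `images_per_patient` range,
#' last patient absorbs the remainder), samples per-image texture parameters
#' from the class-conditional bounds, and renders every image with its
#' site's acquisition physics. Per-site per-class image counts equal the
#' profiles exactly; patient id sets of different sites are disjoint.
#' Deterministic given `seed` (bit-exact pixels).
#'
#' @param profiles List of [site_profile()] objects (see
#'   [default_site_profiles()]).
#' @param seed Integer root seed.
#' @param bounds Texture bounds tibble, default [texture_bounds()].
#' @param render Set `FALSE` to skip rendering and return the manifest only
#'   (empty `pixels` entries); useful for fast count/split checks.
#' @return A `col6_dataset` tibble with columns `image_id`, `site_id`,
#'   `patient_id`, `class`, `class_index`, `pixels`.
#' @examples
#' manifest <- generate_federated_dataset(default_site_profiles(), seed = 1,
#'                                        render = FALSE)
#' dplyr::count(manifest, site_id)
#' @export
generate_federated_dataset <- function(profiles, seed,
                                       bounds = texture_bounds(),
                                       render = TRUE) {
  if (length(profiles) < 1) stop("need at least one site profile",
                                 call. = FALSE)
  labs <- class_labels()
  rows <- list()
  counter <- 0L
  for (prof in profiles) {
    pat_counter <- 0L
    for (cls in labs) {
      n_img <- prof$class_counts[[cls]]
      n_pat <- prof$patients_per_class[[cls]]
      if (n_img == 0L) next
      if (n_pat == 0L) {
        stop("site ", prof$site_id, " has images but no patients for class ",
             cls, call. = FALSE)
      }
      sizes <- with_seed(derive_seed(seed, counter),
                         patient_image_sizes(n_img, n_pat,
                                             prof$images_per_patient))
      counter <- counter + 1L
      for (k in seq_len(n_pat)) {
        pat_counter <- pat_counter + 1L
        pid <- sprintf("%s_P%03d", prof$site_id, pat_counter)
        for (j in seq_len(sizes[k])) {
          counter <- counter + 1L
          rows[[length(rows) + 1L]] <- tibble::tibble(
            site_id = prof$site_id, patient_id = pid, class = cls,
            counter = counter)
        }
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$image_id <- sprintf("%s_I%04d", out$site_id,
                          stats::ave(seq_len(nrow(out)), out$site_id,
                                     FUN = seq_along))
  out$class_index <- class_index(out$class)
  prof_by_id <- stats::setNames(profiles,
                                vapply(profiles, `[[`, "", "site_id"))
  if (render) {
    out$pixels <- purrr::pmap(
      list(out$class, out$site_id, out$counter),
      function(cls, sid, ctr) {
        params <- sample_texture_params(cls, derive_seed(seed, 2 * ctr),
                                        bounds = bounds)
        render_image(params, prof_by_id[[sid]],
                     seed = derive_seed(seed, 2 * ctr + 1))
      })
  } else {
    out$pixels <- vector("list", nrow(out))
  }
  out <- out[, c("image_id", "site_id", "patient_id", "class", "class_index",
                 "pixels")]
  out <- tibble::new_tibble(out, class = "col6_dataset", nrow = nrow(out))
  attr(out, "seed") <- seed
  out
}

# One stratified-random attempt at picking whole patients whose image counts
# sum to `target`: cycle classes in random order, within each class pick a
# random unused patient that fits, preferring picks that do not strand an
# unreachable remainder of 1.
pick_patients_once <- function(pat, target) {
  pat <- pat[sample.int(nrow(pat)), , drop = FALSE]
  classes <- sample(unique(pat$class))
  chosen <- character(0)
  remaining <- target
  used <- rep(FALSE, nrow(pat))
  ci <- 1L
  stall <- 0L
  while (remaining > 0 && stall < length(classes)) {
    cls <- classes[ci]
    ci <- ci %% length(classes) + 1L
    cand <- which(!used & pat$class == cls & pat$n <= remaining)
    good <- cand[remaining - pat$n[cand] != 1L]
    pick <- if (length(good)) good[1] else if (length(cand)) cand[1] else NA
    if (is.na(pick)) { stall <- stall + 1L; next }
    stall <- 0L
    used[pick] <- TRUE
    chosen <- c(chosen, pat$patient_id[pick])
    remaining <- remaining - pat$n[pick]
  }
  list(chosen = chosen, remaining = remaining)
}

#' Split a dataset at the patient level
#'
#' Selects whole patients into the test partition, stratified over classes
#' as evenly as achievable, until each site's requested test image count is
#' met. Selection is randomized and restarted (up to 60 attempts per site)
#' until the count is met exactly; if no exact combination is found the last
#' patient minimally exceeds it. No patient ever appears in both partitions.
#' Deterministic given `seed`.
#'
#' @param data A `col6_dataset` tibble.
#' @param test_counts Named vector, site id -> test image count.
#' @param seed Integer seed.
#' @return The dataset with an added `partition` column (`"train"` /
#'   `"test"`).
#' @examples
#' d <- generate_federated_dataset(default_site_profiles(), 1, render = FALSE)
#' d <- split_patient_level(d, c(NIH = 20, UCL = 4), seed = 1)
#' table(d$partition)
#' @export
split_patient_level <- function(data, test_counts, seed) {
  stopifnot(all(names(test_counts) %in% unique(data$site_id)))
  test_patients <- character(0)
  for (sid in names(test_counts)) {
    target <- test_counts[[sid]]
    if (target == 0) next
    pat <- data |>
      dplyr::filter(.data$site_id == sid) |>
      dplyr::count(.data$patient_id, .data$class, name = "n")
    if (target > sum(pat$n)) {
      stop("site ", sid, ": requested test count ", target,
           " exceeds available images (", sum(pat$n), ")", call. = FALSE)
    }
    res <- with_seed(derive_seed(seed, match(sid, names(test_counts))), {
      best <- NULL
      for (attempt in 1:60) {
        r <- pick_patients_once(pat, target)
        if (is.null(best) || r$remaining >= 0 && r$remaining <
              best$remaining) best <- r
        if (best$remaining == 0) break
      }
      if (best$remaining > 0) {
        # minimal excess: close the gap with the smallest remaining patient
        left <- pat[!pat$patient_id %in% best$chosen, , drop = FALSE]
        left <- left[left$n >= best$remaining, , drop = FALSE]
        if (nrow(left) == 0) {
          stop("site ", sid, ": cannot reach test count ", target,
               call. = FALSE)
        }
        add <- left$patient_id[which.min(left$n)]
        best$chosen <- c(best$chosen, add)
      }
      best$chosen
    })
    test_patients <- c(test_patients, res)
  }
  data$partition <- ifelse(data$patient_id %in% test_patients, "test",
                           "train")
  data
}

#' @rdname split_patient_level
#' @param partition Partition to extract, `"train"` or `"test"`.
#' @export
partition_images <- function(data, partition) {
  stopifnot("partition" %in% names(data))
  data[data$partition == partition, , drop = FALSE]
}
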