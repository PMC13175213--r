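# Standard-format I/O: 8-bit RGB PNGs + CSV manifest, YAML scenario configs.

#' Write a dataset to disk as PNGs with a CSV manifest
#'
#' Images go to `<out_dir>/images/<image_id>.png` as 8-bit RGB PNG; the
#' manifest `<out_dir>/manifest.csv` has columns
#' `image_path,patient_id,site_id,class_label` (plus `partition` when
#' present).
#'
#' @param data A `col6_dataset` tibble with rendered `pixels`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest tibble.
#' @export
write_dataset <- function(data, out_dir) {
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path("images", paste0(data$image_id, ".png"))
  purrr::walk2(data$pixels, paths, function(px, pth) {
    png::writePNG(px, file.path(out_dir, pth))
  })
  manifest <- tibble::tibble(image_path = paths,
                             patient_id = data$patient_id,
                             site_id = data$site_id,
                             class_label = data$class)
  if ("partition" %in% names(data)) manifest$partition <- data$partition
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read a dataset from a manifest CSV and image directory
#'
#' Accepts the layout written by [write_dataset()], or any user-supplied
#' directory of RGB PNGs with a manifest holding
#' `image_path,patient_id,site_id,class_label`.
#'
#' @param manifest_path Path to the manifest CSV; image paths are resolved
#'   relative to its directory.
#' @return A `col6_dataset` tibble.
#' @export
read_dataset <- function(manifest_path) {
  base <- dirname(manifest_path)
  m <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("image_path", "patient_id", "site_id", "class_label")
  if (!all(req %in% names(m))) {
    stop("manifest must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    image_id = sub("\\.png$", "", basename(m$image_path)),
    site_id = m$site_id,
    patient_id = m$patient_id,
    class = m$class_label,
    class_index = class_index(m$class_label),
    pixels = purrr::map(m$image_path, function(p) {
      px <- png::readPNG(file.path(base, p))
      if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
      px[, , 1:3, drop = FALSE]
    })
  )
  if ("partition" %in% names(m)) out$partition <- m$partition
  tibble::new_tibble(out, class = "col6_dataset", nrow = nrow(out))
}

# Serialize site profiles to / from plain lists for YAML configs.
profile_to_list <- function(p) {
  list(site_id = p$site_id, brightness_gain = p$brightness_gain,
       blur_sigma = p$blur_sigma, noise_sd = p$noise_sd,
       background_level = p$background_level,
       native_size = as.integer(p$native_size),
       class_counts = as.list(p$class_counts),
       patients_per_class = as.list(p$patients_per_class),
       images_per_patient = as.integer(p$images_per_patient))
}

profile_from_list <- function(l) {
  site_profile(l$site_id,
               brightness_gain = l$brightness_gain,
               blur_sigma = l$blur_sigma,
               noise_sd = l$noise_sd,
               background_level = l$background_level,
               native_size = unlist(l$native_size),
               class_counts = unlist(l$class_counts),
               patients_per_class = unlist(l$patients_per_class),
               images_per_patient = unlist(l$images_per_patient))
}

#' Read / write scenario configurations as YAML
#'
#' A scenario file mirrors the [site_profile()] fields for each site.
#'
#' @param profiles List of [site_profile()] objects.
#' @param path File path (`.yaml`).
#' @return `read_scenario()` returns a named list of [site_profile()]s.
#' @export
write_scenario <- function(profiles, path) {
  yaml::write_yaml(list(sites = lapply(unname(profiles), profile_to_list)),
                   path)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  profs <- lapply(cfg$sites, profile_from_list)
  stats::setNames(profs, vapply(profs, `[[`, "", "site_id"))
}
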