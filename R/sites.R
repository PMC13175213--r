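#' Acquisition-site profile
#'
#' A site profile bundles the acquisition physics of one imaging site (node)
#' with its per-class patient and image counts. Site physics are applied to
#' every rendered image in a fixed order: background addition, Gaussian blur,
#' brightness gain, additive Gaussian noise, clipping to [0, 1]. Differences
#' between profiles are what make the two-site benchmark non-IID: both
#' covariate shift (brightness, blur, noise, resolution) and label shift
#' (class proportions).
#'
#' @param site_id Site name, e.g. `"NIH"`.
#' @param brightness_gain Multiplicative gain (> 0).
#' @param blur_sigma Gaussian PSF sigma in px (>= 0).
#' @param noise_sd SD of additive Gaussian read-out noise (>= 0), intensity
#'   units.
#' @param background_level Constant background in [0, 1).
#' @param native_size Native acquisition size, `c(height, width)` in px
#'   (>= 32 each).
#' @param class_counts Named integer vector: images per class. Names must be
#'   the four canonical class labels.
#' @param patients_per_class Named integer vector: patients per class; each
#'   entry must not exceed the class image count.
#' @param images_per_patient Length-2 integer range; per-patient image counts
#'   are drawn uniformly from it, then the last patient of each class absorbs
#'   the rounding so totals match `class_counts` exactly.
#' @return An object of class `site_profile`.
#' @examples
#' site_profile("toy", class_counts = c(control = 4, glycine_substitution = 4,
#'   pseudoexon_insertion = 4, exon_skipping = 4),
#'   patients_per_class = c(control = 2, glycine_substitution = 2,
#'   pseudoexon_insertion = 2, exon_skipping = 2))
#' @export
site_profile <- function(site_id,
                         brightness_gain = 1,
                         blur_sigma = 1,
                         noise_sd = 0.02,
                         background_level = 0.08,
                         native_size = c(320L, 320L),
                         class_counts,
                         patients_per_class,
                         images_per_patient = c(2L, 6L)) {
  stopifnot(is.character(site_id), nzchar(site_id),
            brightness_gain > 0, blur_sigma >= 0, noise_sd >= 0,
            background_level >= 0, background_level < 1,
            length(native_size) == 2)
  labs <- class_labels()
  if (!setequal(names(class_counts), labs) ||
      !setequal(names(patients_per_class), labs)) {
    stop("class_counts and patients_per_class must be named by the four ",
         "canonical class labels", call. = FALSE)
  }
  class_counts <- class_counts[labs]
  patients_per_class <- patients_per_class[labs]
  if (any(class_counts < 0) || any(patients_per_class < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(patients_per_class > class_counts)) {
    bad <- labs[patients_per_class > class_counts]
    stop("patients_per_class exceeds class image count for: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(site_id = site_id,
         brightness_gain = brightness_gain,
         blur_sigma = blur_sigma,
         noise_sd = noise_sd,
         background_level = background_level,
         native_size = as.integer(native_size),
         class_counts = stats::setNames(as.integer(class_counts), labs),
         patients_per_class = stats::setNames(as.integer(patients_per_class),
                                              labs),
         images_per_patient = as.integer(images_per_patient)),
    class = "site_profile"
  )
}

#' @export
print.site_profile <- function(x, ...) {
  cat("<site_profile> ", x$site_id,
      ": ", sum(x$class_counts), " images / ", sum(x$patients_per_class),
      " patients, ", paste(x$native_size, collapse = "x"), " px\n",
      "  gain ", x$brightness_gain, ", blur ", x$blur_sigma,
      ", noise ", x$noise_sd, ", background ", x$background_level, "\n",
      sep = "")
  print(x$class_counts)
  invisible(x)
}

#' Default two-site benchmark scenario
#'
#' Two sites with the published image distribution: a large node (`NIH`,
#' 300 images: 84 control, 94 glycine substitution, 51 pseudoexon insertion,
#' 71 exon skipping) and a small node (`UCL`, 31 images: 7/5/8/11), 331
#' images from 90 patients in total. The small site is rendered brighter,
#' blurrier, noisier and at a different native resolution than the large
#' site, so the federation is non-IID in both acquisition physics and label
#' proportions. Patient counts per site (81 vs 9) keep roughly 3.7 images
#' per patient at both sites.
#'
#' @return A named list of two [site_profile()] objects.
#' @examples
#' profs <- default_site_profiles()
#' sum(profs$NIH$class_counts) + sum(profs$UCL$class_counts)  # 331
#' @export
default_site_profiles <- function() {
  list(
    NIH = site_profile(
      "NIH",
      brightness_gain = 1.0, blur_sigma = 1.0, noise_sd = 0.02,
      background_level = 0.08, native_size = c(320L, 320L),
      class_counts = c(control = 84, glycine_substitution = 94,
                       pseudoexon_insertion = 51, exon_skipping = 71),
      patients_per_class = c(control = 23, glycine_substitution = 25,
                             pseudoexon_insertion = 14, exon_skipping = 19)
    ),
    UCL = site_profile(
      "UCL",
      brightness_gain = 1.4, blur_sigma = 2.5, noise_sd = 0.08,
      background_level = 0.18, native_size = c(272L, 272L),
      class_counts = c(control = 7, glycine_substitution = 5,
                       pseudoexon_insertion = 8, exon_skipping = 11),
      patients_per_class = c(control = 2, glycine_substitution = 2,
                             pseudoexon_insertion = 2, exon_skipping = 3)
    )
  )
}
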