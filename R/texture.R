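#' Class-conditional texture parameter bounds
#'
#' Each phenotype class is rendered from six texture parameters drawn
#' uniformly from class-specific bounds. The bounds encode the qualitative
#' phenotypes of collagen VI matrix staining: controls lay down a dense,
#' well-aligned, continuous beaded-filament network; glycine substitutions
#' give a speckled, poorly oriented matrix with many puncta; the pseudoexon
#' insertion yields an intermediate-density network with attenuated beading;
#' exon skipping gives a sparse, highly fragmented network. Bounds of
#' neighbouring classes deliberately overlap so the four-class task is
#' learnable but not trivially saturated.
#'
#' Parameters and units: `filament_density` (filaments per 1e4 px^2),
#' `orientation_coherence` (0-1; concentration of filament orientations),
#' `bead_spacing` (px; period of the intensity beading along filaments),
#' `bead_contrast` (0-1; modulation depth of the beading),
#' `fragmentation` (0-1; probability a filament is broken into segments),
#' `puncta_rate` (puncta per 1e4 px^2).
#'
#' @return A tibble with columns `class`, `param`, `lower`, `upper`.
#' @export
texture_bounds <- function() {
  b <- function(cls, density, coherence, spacing, contrast, fragmentation,
                puncta) {
    tibble::tibble(
      class = cls,
      param = c("filament_density", "orientation_coherence", "bead_spacing",
                "bead_contrast", "fragmentation", "puncta_rate"),
      lower = c(density[1], coherence[1], spacing[1], contrast[1],
                fragmentation[1], puncta[1]),
      upper = c(density[2], coherence[2], spacing[2], contrast[2],
                fragmentation[2], puncta[2])
    )
  }
  dplyr::bind_rows(
    b("control",
      density = c(3.2, 4.6), coherence = c(0.72, 0.95), spacing = c(8, 14),
      contrast = c(0.45, 0.75), fragmentation = c(0.00, 0.12),
      puncta = c(0.5, 2.0)),
    b("glycine_substitution",
      density = c(2.5, 3.8), coherence = c(0.25, 0.50), spacing = c(8, 14),
      contrast = c(0.35, 0.65), fragmentation = c(0.05, 0.25),
      puncta = c(8.0, 14.0)),
    b("pseudoexon_insertion",
      density = c(2.2, 3.3), coherence = c(0.50, 0.72), spacing = c(10, 18),
      contrast = c(0.02, 0.20), fragmentation = c(0.10, 0.30),
      puncta = c(0.5, 3.0)),
    b("exon_skipping",
      density = c(0.8, 1.8), coherence = c(0.45, 0.75), spacing = c(8, 14),
      contrast = c(0.30, 0.60), fragmentation = c(0.50, 0.80),
      puncta = c(1.0, 4.0))
  )
}

#' Sample texture parameters for one image
#'
#' Draws each texture parameter uniformly from the class-conditional bounds
#' (see [texture_bounds()]). Deterministic given `seed`.
#'
#' @param class A class label (see [pathogenic_classes()]).
#' @param seed Integer seed.
#' @param bounds Bounds tibble as returned by [texture_bounds()]; override to
#'   change the phenotype model.
#' @return A one-row tibble with the six texture parameters and a `class`
#'   column.
#' @examples
#' sample_texture_params("control", seed = 1)
#' @export
sample_texture_params <- function(class, seed, bounds = texture_bounds()) {
  if (!class %in% class_labels()) {
    stop("unknown class label: ", class, call. = FALSE)
  }
  cb <- bounds[bounds$class == class, , drop = FALSE]
  vals <- with_seed(seed, stats::runif(nrow(cb), cb$lower, cb$upper))
  out <- tibble::as_tibble(as.list(stats::setNames(vals, cb$param)))
  dplyr::bind_cols(tibble::tibble(class = class), out)
}
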