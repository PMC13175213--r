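# Small two-site scenario for fast module tests: same structure as the
# default benchmark (two heterogeneous sites, all four classes, multi-image
# patients) at a fraction of the size.
tiny_profiles <- function() {
  list(
    A = site_profile(
      "A",
      brightness_gain = 1, blur_sigma = 0.8, noise_sd = 0.02,
      background_level = 0.08, native_size = c(48L, 48L),
      class_counts = c(control = 4, glycine_substitution = 4,
                       pseudoexon_insertion = 4, exon_skipping = 4),
      patients_per_class = c(control = 2, glycine_substitution = 2,
                             pseudoexon_insertion = 2, exon_skipping = 2)),
    B = site_profile(
      "B",
      brightness_gain = 1.3, blur_sigma = 1.5, noise_sd = 0.05,
      background_level = 0.15, native_size = c(40L, 40L),
      class_counts = c(control = 2, glycine_substitution = 2,
                       pseudoexon_insertion = 2, exon_skipping = 2),
      patients_per_class = c(control = 1, glycine_substitution = 1,
                             pseudoexon_insertion = 1, exon_skipping = 1))
  )
}

# Smooth asymmetric test image: a Gaussian blob off-center plus a ramp.
smooth_image <- function(n = 64) {
  y <- matrix(rep(seq_len(n), n), n)
  x <- t(y)
  blob <- exp(-((x - n / 3)^2 + (y - n / 2.2)^2) / (2 * (n / 8)^2))
  base <- 0.15 + 0.5 * blob + 0.2 * x / n
  array(c(0.4 * base, base, 0.25 * base), c(n, n, 3)) |> pmin(1)
}

rand_image <- function(seed, n = 32) {
  set.seed(seed)
  array(runif(n * n * 3), c(n, n, 3))
}

# Independent confusion-matrix tally: explicit double loop, no vectorized
# sharing with the implementation.
oracle_confusion <- function(y_true, y_pred, k) {
  cm <- matrix(0L, k, k)
  for (i in 1:k) for (j in 1:k) {
    n <- 0L
    for (t in seq_along(y_true)) {
      if (y_true[t] == i && y_pred[t] == j) n <- n + 1L
    }
    cm[i, j] <- n
  }
  cm
}

# Independent per-class metrics from an explicit TP/FP/FN tally.
oracle_prf <- function(y_true, y_pred, k) {
  out <- matrix(0, k, 3)
  for (c in 1:k) {
    tp <- sum(y_true == c & y_pred == c)
    fp <- sum(y_true != c & y_pred == c)
    fn <- sum(y_true == c & y_pred != c)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[c, ] <- c(p, r, f)
  }
  colnames(out) <- c("precision", "recall", "f1")
  out
}
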