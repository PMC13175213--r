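# Frozen input-scaling layer of the feature backbone.
#
# The raw texture descriptor mixes feature groups of very different
# magnitudes (histogram proportions, gradient statistics, bounded ratios),
# which conditions gradient descent poorly. As in any frozen pretrained
# backbone whose final layers carry fixed normalization statistics, the
# descriptor therefore ships a fixed per-feature affine map z = (x - c) / s.
# The constants below were computed once over a reference pool of synthetic
# images spanning both default site profiles, all four classes and all
# augmentation variants, then rounded and frozen; they are design constants
# of the backbone, not fitted during any experiment. SDs are floored at
# 0.005 so that near-constant features (rarely populated histogram bins)
# cannot blow up.

.feat_center <- c(
  0.01826, 0.4055, 0.09641, 0.1265, 0.1727, 0.09787, 0.05078, 0.02271,
  0.007248, 0.001674, 0.0002924, 4.171e-05, 4.768e-06, 3.815e-07,
  3.179e-08, 0, 0.01735, 0.3686, 0.09019, 0.1282, 0.1668, 0.1088, 0.06367,
  0.03181, 0.0142, 0.006114, 0.002575, 0.001029, 0.0004133, 0.0001555,
  5.728e-05, 2.969e-05, 0.01923, 0.4264, 0.08215, 0.13, 0.1733, 0.09313,
  0.04802, 0.02044, 0.005964, 0.001201, 0.0001866, 2.41e-05, 2.098e-06,
  2.861e-07, 3.179e-08, 0, 0.1981, 0.04074, 0.2147, 0.0647, 0.1937,
  0.0372, 0.3753, 0.2606, 0.7326, 0.214, 0.308, 0.2628, 0.6809, 0.1454,
  0.2717, 0.2582, 0.6412, 0.1284, 0.135, 0.1251, 0.1224, 0.1147, 0.1239,
  0.1251, 0.1286, 0.1252, 0.2647, 0.9472, 0.346, 0.7224, 0.1226, 0.5662,
  0.5272, 0.5265)

.feat_scale <- c(
  0.0284, 0.4167, 0.1243, 0.1534, 0.1934, 0.1185, 0.09599, 0.05489,
  0.01994, 0.005, 0.005, 0.005, 0.005, 0.005, 0.005, 0.005, 0.02708,
  0.3787, 0.1038, 0.1207, 0.1627, 0.1071, 0.08619, 0.05614, 0.02939,
  0.01478, 0.007268, 0.005, 0.005, 0.005, 0.005, 0.005, 0.02981, 0.4365,
  0.1294, 0.1667, 0.1921, 0.1192, 0.09475, 0.0508, 0.01656, 0.005, 0.005,
  0.005, 0.005, 0.005, 0.005, 0.005, 0.1071, 0.0222, 0.1103, 0.02067,
  0.1063, 0.0238, 0.1771, 0.07239, 0.2765, 0.1675, 0.1045, 0.08486,
  0.2178, 0.08385, 0.0946, 0.07866, 0.2053, 0.08124, 0.06323, 0.06398,
  0.06301, 0.05274, 0.05126, 0.06384, 0.06846, 0.05784, 0.1794, 0.0612,
  0.09153, 0.207, 0.04047, 0.08191, 0.1813, 0.19)

#' Frozen feature-scaling constants
#'
#' The fixed per-feature centering and scaling constants applied by
#' [extract_features()] (when `scale = TRUE`) on top of the raw texture
#' descriptor. Shared by every node and every arm, so federated and
#' centralized training see identically scaled inputs.
#'
#' @return Tibble with columns `feature`, `center`, `scale`.
#' @export
feature_scaling <- function() {
  tibble::tibble(feature = sprintf("feat_%03d", seq_along(.feat_center)),
                 center = .feat_center, scale = .feat_scale)
}

scale_feature_matrix <- function(X) {
  if (ncol(X) != length(.feat_center)) {
    stop("feature matrix has ", ncol(X), " columns; scaling layer expects ",
         length(.feat_center), call. = FALSE)
  }
  sweep(sweep(X, 2, .feat_center, "-"), 2, .feat_scale, "/")
}
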