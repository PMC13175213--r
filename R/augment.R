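# Preprocessing and training-set augmentation.
#
# Fixed pipeline order: resize_normalize() first, then the augmentation
# variants (rotations, horizontal flip, HSV value scaling). Augmentation is
# applied to the training partition only; validation/test images are only
# resized and normalized.

#' Resize and normalize an image
#'
#' Bilinear resize to `size`, then normalization to [0, 1]: 8-bit inputs
#' (values above 1) are divided by 255, inputs already in [0, 1] are left on
#' their scale. A `size`-shaped input already in [0, 1] is returned
#' unchanged.
#'
#' @param image H x W x 3 array.
#' @param size Target `c(height, width)`, default `c(256, 256)`.
#' @return A `size[1]` x `size[2]` x 3 array in [0, 1].
#' @export
resize_normalize <- function(image, size = c(256L, 256L)) {
  stopifnot_image(image)
  d <- dim(image)
  if (d[1] < 2 || d[2] < 2) stop("image too small to resize", call. = FALSE)
  if (max(image) > 1) image <- image / 255
  if (d[1] == size[1] && d[2] == size[2]) return(image)
  out <- EBImage::imageData(
    EBImage::resize(EBImage::Image(image, colormode = "Color"),
                    w = size[1], h = size[2]))
  out[out < 0] <- 0
  out[out > 1] <- 1
  out
}

rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Reflect-pad a matrix by `p` pixels on every side.
reflect_pad <- function(m, p) {
  n <- nrow(m); k <- ncol(m)
  ri <- c(rev(seq_len(min(p, n))), seq_len(n),
          n - seq_len(min(p, n)) + 1)
  ci <- c(rev(seq_len(min(p, k))), seq_len(k),
          k - seq_len(min(p, k)) + 1)
  m[ri, ci, drop = FALSE]
}

# Bilinear sample matrix `m` at (rows ys, cols xs); coordinates must lie
# inside [1, nrow] x [1, ncol].
bilinear_sample <- function(m, ys, xs) {
  n <- nrow(m)
  y1 <- pmin(pmax(floor(ys), 1), nrow(m) - 1)
  x1 <- pmin(pmax(floor(xs), 1), ncol(m) - 1)
  fy <- ys - y1; fx <- xs - x1
  i11 <- (x1 - 1) * n + y1
  m[i11] * (1 - fy) * (1 - fx) + m[i11 + 1] * fy * (1 - fx) +
    m[i11 + n] * (1 - fy) * fx + m[i11 + n + 1] * fy * fx
}

#' Rotate an image by a multiple of 45 degrees
#'
#' Right-angle multiples are exact index permutations
#' (counter-clockwise). Odd multiples of 45 degrees use bilinear
#' interpolation about the image center; the image is reflect-padded first
#' and center-cropped after, so corners that leave the frame are filled with
#' mirrored content rather than black (which would otherwise let a
#' classifier recognize augmented images by their corners).
#'
#' @param image H x W x 3 array.
#' @param angle_deg Rotation angle, any multiple of 45.
#' @return Array of the same shape.
#' @export
rotate_image <- function(image, angle_deg) {
  stopifnot_image(image)
  if (angle_deg %% 45 != 0) {
    stop("angle must be a multiple of 45 degrees, got ", angle_deg,
         call. = FALSE)
  }
  a <- angle_deg %% 360
  if (a == 0) return(image)
  if (a %% 90 == 0) {
    k <- a / 90
    for (i in seq_len(k)) {
      image <- array(apply(image, 3, rot90_ccw),
                     dim = c(dim(image)[2], dim(image)[1], 3))
    }
    return(image)
  }
  H <- dim(image)[1]; W <- dim(image)[2]
  p <- ceiling(0.5 * (sqrt(H^2 + W^2) - min(H, W))) + 2L
  th <- a * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yy <- rep(seq_len(H), times = W) - cy
  xx <- rep(seq_len(W), each = H) - cx
  # inverse map: output pixel pulls from source rotated by -angle
  ys <- cy + cos(th) * yy + sin(th) * xx + p
  xs <- cx - sin(th) * yy + cos(th) * xx + p
  out <- array(0, dim(image))
  for (ch in 1:3) {
    out[, , ch] <- matrix(bilinear_sample(reflect_pad(image[, , ch], p),
                                          ys, xs), H, W)
  }
  out
}

#' Horizontal flip
#'
#' Reverses the column order of an image; an exact involution.
#'
#' @param image H x W x 3 array.
#' @return Array of the same shape.
#' @export
hflip <- function(image) {
  stopifnot_image(image)
  image[, dim(image)[2]:1, , drop = FALSE]
}

# Vectorized HSV -> RGB with h, s, v in [0, 1]; sextant selection done
# arithmetically (logical masks) to stay fast on whole images.
hsv_to_rgb <- function(h, s, v) {
  h6 <- (h * 6) %% 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- v * (i == 0 | i == 5) + q * (i == 1) + p * (i == 2 | i == 3) +
    t * (i == 4)
  g <- t * (i == 0) + v * (i == 1 | i == 2) + q * (i == 3) +
    p * (i == 4 | i == 5)
  b <- p * (i == 0 | i == 1) + t * (i == 2) + v * (i == 3 | i == 4) +
    q * (i == 5)
  list(r = r, g = g, b = b)
}

#' Brightness augmentation in HSV space
#'
#' Converts RGB to HSV, scales the Value channel by `factor`, clips it to
#' [0, 1], and converts back to RGB. Hue and saturation of unclipped pixels
#' are preserved.
#'
#' @param image H x W x 3 array in [0, 1].
#' @param factor Positive scale for the V channel.
#' @return Array of the same shape in [0, 1].
#' @export
hsv_brightness <- function(image, factor) {
  stopifnot_image(image)
  if (factor <= 0) stop("brightness factor must be > 0", call. = FALSE)
  # The HSV round trip reduces to a per-pixel rescale: V is max(R, G, B),
  # and multiplying all channels by min(factor * V, 1) / V leaves H and S
  # unchanged while scaling (and clipping) V — algebraically identical to
  # rgb2hsv -> scale V -> hsv2rgb, without the conversion cost. The
  # equivalence is pinned against an explicit colorspace-conversion oracle
  # in the test-suite.
  v <- pmax(image[, , 1], image[, , 2], image[, , 3])
  scale <- ifelse(v > 0, pmin(v * factor, 1) / v, 1)
  image * as.vector(scale)
}

#' Augmentation configuration
#'
#' Defaults mirror the published pipeline: one 45-degree rotation,
#' horizontal flip, and HSV value scaling by 1.25 and 1.5, on 256 x 256
#' inputs. All multiples of 45 degrees are accepted in `rotation_angles`.
#'
#' @param rotation_angles Angles in degrees, multiples of 45 within
#'   45..315.
#' @param apply_hflip Add a horizontally flipped variant?
#' @param brightness_factors Positive HSV value-channel factors.
#' @param target_size Expected input size `c(height, width)`.
#' @return An `augmentation_config` object.
#' @export
augmentation_config <- function(rotation_angles = 45,
                                apply_hflip = TRUE,
                                brightness_factors = c(1.25, 1.5),
                                target_size = c(256L, 256L)) {
  if (length(rotation_angles) &&
      any(rotation_angles %% 45 != 0 | rotation_angles < 45 |
            rotation_angles > 315)) {
    stop("rotation_angles must be multiples of 45 in 45..315", call. = FALSE)
  }
  if (any(brightness_factors <= 0)) {
    stop("brightness_factors must be > 0", call. = FALSE)
  }
  structure(list(rotation_angles = rotation_angles,
                 apply_hflip = isTRUE(apply_hflip),
                 brightness_factors = brightness_factors,
                 target_size = as.integer(target_size)),
            class = "augmentation_config")
}

# Variants of one preprocessed image under a config: named list, original
# first.
augment_variants <- function(image, cfg) {
  out <- list(original = image)
  for (a in cfg$rotation_angles) {
    out[[paste0("rot", a)]] <- rotate_image(image, a)
  }
  if (cfg$apply_hflip) out$hflip <- hflip(image)
  for (f in cfg$brightness_factors) {
    out[[paste0("bright", f)]] <- hsv_brightness(image, f)
  }
  out
}

#' Augment a training set
#'
#' Emits, per input image, the original plus one variant per configured
#' rotation angle, one horizontally flipped variant if enabled, and one
#' variant per brightness factor (default config: 5 images per input).
#' Labels, patient and site metadata are copied to every variant. Refuses to
#' run on rows tagged `partition == "test"`: augmentation is a
#' training-only transform.
#'
#' @param data A `col6_dataset` tibble whose `pixels` are already
#'   resized/normalized to `cfg$target_size`.
#' @param cfg An [augmentation_config()].
#' @return A tibble with one row per variant and an added `variant` column.
#' @export
augment_training_set <- function(data, cfg = augmentation_config()) {
  if ("partition" %in% names(data) && any(data$partition == "test")) {
    stop("augmentation must not be applied to a test partition",
         call. = FALSE)
  }
  if (nrow(data) == 0) {
    out <- data
    out$variant <- character(0)
    return(out)
  }
  ok <- vapply(data$pixels, function(px) {
    all(dim(px)[1:2] == cfg$target_size)
  }, logical(1))
  if (!all(ok)) {
    stop("images must be preprocessed to ",
         paste(cfg$target_size, collapse = " x "),
         " before augmentation; run resize_normalize() first", call. = FALSE)
  }
  rows <- purrr::map(seq_len(nrow(data)), function(i) {
    vars <- augment_variants(data$pixels[[i]], cfg)
    meta <- data[rep(i, length(vars)), setdiff(names(data), "pixels"),
                 drop = FALSE]
    meta$variant <- names(vars)
    meta$pixels <- unname(vars)
    meta
  })
  dplyr::bind_rows(rows)
}
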