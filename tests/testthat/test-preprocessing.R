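test_that("resize_normalize produces 256x256x3 in [0,1] and preserves constants", {
  img <- rand_image(1, n = 40)
  out <- resize_normalize(img)
  expect_equal(dim(out), c(256, 256, 3))
  expect_true(all(out >= 0 & out <= 1))

  const8 <- array(128, c(40, 40, 3))
  out8 <- resize_normalize(const8)
  expect_true(all(abs(out8 - 128 / 255) < 1e-9))

  already <- rand_image(2, n = 256)
  expect_identical(resize_normalize(already), already)

  expect_error(resize_normalize(matrix(0, 10, 10)), "3")
})

test_that("right-angle rotations are exact index permutations", {
  img <- rand_image(3, n = 8)
  # independent oracle: out[i, j] = in[j, H - i + 1] for one CCW quarter turn
  oracle90 <- array(0, dim(img))
  H <- dim(img)[1]
  for (ch in 1:3) {
    for (i in seq_len(H)) for (j in seq_len(H)) {
      oracle90[i, j, ch] <- img[j, H - i + 1, ch]
    }
  }
  expect_identical(rotate_image(img, 90), oracle90)
  expect_identical(rotate_image(img, 360), img)
  expect_identical(rotate_image(rotate_image(img, 180), 180), img)
  expect_error(rotate_image(img, 30), "45")
})

test_that("45-degree rotations compose and stay in frame", {
  img <- smooth_image(64)
  once90 <- rotate_image(img, 90)
  twice45 <- rotate_image(rotate_image(img, 45), 45)
  # interiors agree within interpolation tolerance on a smooth image
  core <- 17:48
  expect_lt(max(abs(once90[core, core, ] - twice45[core, core, ])), 0.02)
  r45 <- rotate_image(img, 45)
  expect_equal(dim(r45), dim(img))
  expect_true(all(r45 >= 0 & r45 <= 1 + 1e-12))
})

test_that("horizontal flip is an exact involution that reverses columns", {
  img <- rand_image(4, n = 16)
  expect_identical(hflip(hflip(img)), img)
  expect_equal(mean(hflip(img)), mean(img))
  grad <- array(c(0.1, 0.5, 0.9), c(1, 3, 1))[, , c(1, 1, 1), drop = FALSE]
  flipped <- hflip(grad)
  expect_equal(as.numeric(flipped[1, , 1]), c(0.9, 0.5, 0.1))
})

test_that("HSV brightness scaling matches a full colorspace-conversion oracle", {
  img <- rand_image(5, n = 24)
  expect_lt(max(abs(hsv_brightness(img, 1) - img)), 1e-6)

  achro <- array(0.4, c(6, 6, 3))
  expect_true(all(abs(hsv_brightness(achro, 1.5) - 0.6) < 1e-9))

  # independent oracle: explicit rgb2hsv -> scale V -> hsv2rgb conversion
  fac <- 1.25
  m <- rbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
             as.vector(img[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 1)
  h <- hsv["h", ]; s <- hsv["s", ]; v <- pmin(hsv["v", ] * fac, 1)
  h6 <- (h * 6) %% 6
  i <- floor(h6); f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  pick <- function(a0, a1, a2, a3, a4, a5) {
    ifelse(i == 0, a0, ifelse(i == 1, a1, ifelse(i == 2, a2,
      ifelse(i == 3, a3, ifelse(i == 4, a4, a5)))))
  }
  oracle <- array(c(pick(v, q, p, p, t, v), pick(t, v, v, q, p, p),
                    pick(p, p, t, v, v, q)), dim(img))
  expect_lt(max(abs(hsv_brightness(img, fac) - oracle)), 1e-9)

  # hue of unclipped pixels is preserved
  dimmed <- img * 0.5
  out <- hsv_brightness(dimmed, 1.25)
  h_in <- grDevices::rgb2hsv(rbind(as.vector(dimmed[, , 1]),
                                   as.vector(dimmed[, , 2]),
                                   as.vector(dimmed[, , 3])),
                             maxColorValue = 1)["h", ]
  h_out <- grDevices::rgb2hsv(rbind(as.vector(out[, , 1]),
                                    as.vector(out[, , 2]),
                                    as.vector(out[, , 3])),
                              maxColorValue = 1)["h", ]
  expect_lt(max(abs(h_in - h_out)), 1e-6)

  expect_error(hsv_brightness(img, 0), "> 0")
})

test_that("training-set augmentation expands counts and copies metadata", {
  d <- generate_federated_dataset(tiny_profiles(), seed = 41)
  d$pixels <- purrr::map(d$pixels, resize_normalize)
  ten <- d[1:10, ]
  aug <- augment_training_set(ten)
  expect_equal(nrow(aug), 50)  # original + rot45 + hflip + 2 brightness
  expect_equal(aug$patient_id, rep(ten$patient_id, each = 5))
  expect_equal(aug$class, rep(ten$class, each = 5))
  expect_true(all(purrr::map_lgl(aug$pixels,
                                 ~ all(.x >= 0 & .x <= 1 + 1e-12))))

  empty <- ten[0, ]
  expect_equal(nrow(augment_training_set(empty)), 0)

  cfg <- augmentation_config()
  expect_setequal(cfg$brightness_factors, c(1.25, 1.5))

  d$partition <- "test"
  expect_error(augment_training_set(d), "test")

  expect_error(augment_training_set(
    dplyr::mutate(ten, pixels = purrr::map(pixels, ~ .x[1:100, 1:100, ])),
    cfg), "resize")
})
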