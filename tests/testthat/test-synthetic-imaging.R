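test_that("texture parameters are drawn inside class-conditional bounds and are seeded", {
  b <- texture_bounds()
  for (cls in class_labels()) {
    cb <- b[b$class == cls, ]
    draws <- purrr::map(1:100, ~ sample_texture_params(cls, seed = .x))
    for (p in cb$param) {
      vals <- purrr::map_dbl(draws, ~ .x[[p]])
      expect_true(all(vals >= cb$lower[cb$param == p]), info = paste(cls, p))
      expect_true(all(vals <= cb$upper[cb$param == p]), info = paste(cls, p))
    }
  }
  expect_identical(sample_texture_params("glycine_substitution", 0),
                   sample_texture_params("glycine_substitution", 0))
  expect_error(sample_texture_params("nonsense", 1), "nonsense")
})

test_that("uniform sampling moments match over many draws", {
  cb <- texture_bounds() |> dplyr::filter(class == "control")
  draws <- purrr::map(1:1000, ~ sample_texture_params("control", seed = .x))
  for (p in cb$param) {
    lo <- cb$lower[cb$param == p]; hi <- cb$upper[cb$param == p]
    vals <- purrr::map_dbl(draws, ~ .x[[p]])
    expect_gte(min(vals), lo)
    expect_lte(max(vals), hi)
    # uniform mean = midpoint; allow 5 Monte-Carlo standard errors
    se <- (hi - lo) / sqrt(12 * length(vals))
    expect_lt(abs(mean(vals) - (lo + hi) / 2), 5 * se)
  }
})

test_that("rendering with no structure gives the constant background times gain", {
  site <- site_profile("flat", brightness_gain = 1.2, blur_sigma = 1.5,
                       noise_sd = 0, background_level = 0.1,
                       native_size = c(48L, 48L),
                       class_counts = c(control = 1, glycine_substitution = 0,
                                        pseudoexon_insertion = 0,
                                        exon_skipping = 0),
                       patients_per_class = c(control = 1,
                                              glycine_substitution = 0,
                                              pseudoexon_insertion = 0,
                                              exon_skipping = 0))
  params <- sample_texture_params("control", 1)
  params$filament_density <- 0
  params$puncta_rate <- 0
  img <- render_image(params, site, seed = 3)
  expect_equal(dim(img), c(48, 48, 3))
  expect_true(all(abs(img - 0.1 * 1.2) < 1e-9))
})

test_that("rendering is bit-exact given a seed and linear in brightness gain", {
  profs <- tiny_profiles()
  params <- sample_texture_params("control", 5)
  expect_identical(render_image(params, profs$A, seed = 9),
                   render_image(params, profs$A, seed = 9))

  base <- profs$A
  base$noise_sd <- 0
  base$brightness_gain <- 0.3
  doubled <- base
  doubled$brightness_gain <- 0.6
  i1 <- render_image(params, base, seed = 11)
  i2 <- render_image(params, doubled, seed = 11)
  expect_lt(max(i2), 1)  # no clipping in this regime
  expect_true(all(abs(i2 - 2 * i1) < 1e-9))
})

test_that("undersized rendering targets are rejected", {
  small <- tiny_profiles()$A
  small$native_size <- c(16L, 16L)
  expect_error(render_image(sample_texture_params("control", 1), small, 1),
               "32")
})

test_that("generated datasets honour the configured counts and patient structure", {
  d <- generate_federated_dataset(tiny_profiles(), seed = 4, render = FALSE)
  tab <- dplyr::count(d, site_id, class)
  expect_true(all(tab$n[tab$site_id == "A"] == 4))
  expect_true(all(tab$n[tab$site_id == "B"] == 2))
  pa <- unique(d$patient_id[d$site_id == "A"])
  pb <- unique(d$patient_id[d$site_id == "B"])
  expect_length(intersect(pa, pb), 0)
  expect_length(pa, 8)
  expect_length(pb, 4)
  one_class <- d |>
    dplyr::distinct(patient_id, class) |>
    dplyr::count(patient_id)
  expect_true(all(one_class$n == 1))

  bad <- tiny_profiles()
  bad$A$patients_per_class[["control"]] <- 10L
  expect_error(generate_federated_dataset(bad, 1, render = FALSE),
               "patients|images")
})

test_that("the default scenario reproduces the published image distribution", {
  d <- generate_federated_dataset(default_site_profiles(), seed = 1,
                                  render = FALSE)
  expect_equal(nrow(d), 331)
  expect_equal(sum(d$site_id == "NIH"), 300)
  expect_equal(sum(d$site_id == "UCL"), 31)
  expect_equal(sum(d$site_id == "NIH" & d$class == "exon_skipping"), 71)
  expect_equal(sum(d$site_id == "UCL" & d$class == "pseudoexon_insertion"), 8)
  expect_length(unique(d$patient_id), 90)
})

test_that("patient-level splits are disjoint, seeded, and hit the hold-out size", {
  d <- generate_federated_dataset(default_site_profiles(), seed = 2,
                                  render = FALSE)
  s1 <- split_patient_level(d, c(NIH = 20, UCL = 4), seed = 7)
  s2 <- split_patient_level(d, c(NIH = 20, UCL = 4), seed = 7)
  expect_identical(s1$partition, s2$partition)
  expect_equal(sum(s1$partition == "test"), 24)
  expect_length(intersect(s1$patient_id[s1$partition == "train"],
                          s1$patient_id[s1$partition == "test"]), 0)
  expect_error(split_patient_level(d, c(UCL = 40), seed = 1), "UCL")
})

test_that("dataset generation is reproducible bit-for-bit including pixels", {
  d1 <- generate_federated_dataset(tiny_profiles(), seed = 21)
  d2 <- generate_federated_dataset(tiny_profiles(), seed = 21)
  expect_identical(d1$pixels, d2$pixels)
  expect_true(all(purrr::map_lgl(d1$pixels,
                                 ~ all(.x >= 0) && all(.x <= 1))))
})

test_that("PNG + manifest round trip preserves metadata and 8-bit pixels", {
  d <- generate_federated_dataset(tiny_profiles(), seed = 31)
  d <- split_patient_level(d, c(A = 4, B = 2), seed = 1)
  dir <- withr::local_tempdir()
  write_dataset(d, dir)
  back <- read_dataset(file.path(dir, "manifest.csv"))
  expect_equal(back$patient_id, d$patient_id)
  expect_equal(back$class, d$class)
  expect_equal(back$partition, d$partition)
  err <- max(purrr::map2_dbl(d$pixels, back$pixels,
                             ~ max(abs(.x - .y))))
  expect_lt(err, 1 / 255)  # 8-bit quantization only
})

test_that("scenario YAML round trip restores site profiles", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scenario(tiny_profiles(), path)
  back <- read_scenario(path)
  expect_equal(back$A$class_counts, tiny_profiles()$A$class_counts)
  expect_equal(back$B$blur_sigma, tiny_profiles()$B$blur_sigma)
  expect_equal(back$B$native_size, tiny_profiles()$B$native_size)
})
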