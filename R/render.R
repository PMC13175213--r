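# Procedural renderer for fluorescence-matrix-like images.
#
# Collagen VI matrix staining appears as a network of beaded microfibrils
# with occasional bright puncta over a dim background. The renderer draws
# filaments as smoothly curving polylines whose orientations follow a von
# Mises distribution (concentration set by orientation_coherence), modulates
# intensity sinusoidally along each filament (beading), optionally breaks
# filaments into segments (fragmentation), adds Poisson-count puncta, and
# then applies the site's acquisition physics.

# von Mises sampler, Best & Fisher (1979) rejection scheme.
rvonmises <- function(n, mu, kappa) {
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-8) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- mu + sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1))
      i <- i + 1L
    }
  }
  out %% (2 * pi)
}

# Separable Gaussian blur (radius 3*sigma, normalized kernel, mirrored
# boundary) as two banded-matrix products, which hands the work to BLAS.
# The band matrices are cached per (size, sigma). Rows sum to 1, so
# constant images are preserved exactly; identity for sigma = 0.
.blur_cache <- new.env(parent = emptyenv())

blur_band <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  K <- .blur_cache[[key]]
  if (!is.null(K)) return(K)
  r <- max(1L, ceiling(3 * sigma))
  w <- stats::dnorm(-r:r, sd = sigma)
  w <- w / sum(w)
  K <- matrix(0, n, n)
  idx <- seq_len(n)
  for (j in -r:r) {
    src <- idx + j
    src[src < 1] <- 2 - src[src < 1]
    src[src > n] <- 2 * n - src[src > n]
    src <- pmin(pmax(src, 1L), n)
    K[cbind(idx, src)] <- K[cbind(idx, src)] + w[j + r + 1]
  }
  .blur_cache[[key]] <- K
  K
}

blur2d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  blur_band(nrow(x), sigma) %*% x %*% t(blur_band(ncol(x), sigma))
}

# Deposit weighted points into an H x W accumulator with bilinear splatting.
splat <- function(acc, x, y, w) {
  H <- nrow(acc); W <- ncol(acc)
  x1 <- floor(x); y1 <- floor(y)
  fx <- x - x1; fy <- y - y1
  xs <- c(x1, x1 + 1, x1, x1 + 1)
  ys <- c(y1, y1, y1 + 1, y1 + 1)
  ws <- c(w * (1 - fx) * (1 - fy), w * fx * (1 - fy),
          w * (1 - fx) * fy, w * fx * fy)
  keep <- xs >= 1 & xs <= W & ys >= 1 & ys <= H & ws > 0
  if (!any(keep)) return(acc)
  idx <- (xs[keep] - 1) * H + ys[keep]
  tab <- rowsum(ws[keep], group = idx)
  pos <- as.integer(rownames(tab))
  acc[pos] <- acc[pos] + tab[, 1]
  acc
}

# Fraction of signal bleeding into the red and blue channels; the stain is
# imaged predominantly in green so HSV-based augmentation is meaningful.
.bleed <- c(red = 0.30, green = 1.00, blue = 0.12)
# Intrinsic line-spread sigma of the rendered structures (px), applied before
# site physics; gives filaments and puncta a finite width even at blur 0.
.render_psf <- 0.7

#' Render one synthetic immunofluorescence image
#'
#' Draws the filament/puncta texture defined by `params` at the native size
#' of `site`, then applies the site's acquisition physics in order:
#' background addition, Gaussian blur (`blur_sigma`), multiplication by
#' `brightness_gain`, additive Gaussian noise (`noise_sd`), clipping to
#' [0, 1]. The signal sits predominantly in the green channel of the RGB
#' output. Deterministic given `seed`.
#'
#' @param params One-row tibble from [sample_texture_params()] (or a named
#'   list with the same fields).
#' @param site A [site_profile()].
#' @param seed Integer seed.
#' @return An H x W x 3 array with values in [0, 1].
#' @examples
#' site <- default_site_profiles()$NIH
#' img <- render_image(sample_texture_params("control", 1), site, seed = 1)
#' dim(img)
#' @export
render_image <- function(params, site, seed) {
  H <- site$native_size[1]; W <- site$native_size[2]
  if (H < 32 || W < 32) {
    stop("native_size must be at least 32 x 32; texture model undefined below",
         call. = FALSE)
  }
  p <- as.list(params)
  with_seed(seed, {
    area <- H * W / 1e4
    sig <- matrix(0, H, W)

    n_fil <- stats::rpois(1, p$filament_density * area)
    if (n_fil > 0) {
      mu <- stats::runif(1, 0, pi)
      kappa <- 2 * p$orientation_coherence /
        (1 - p$orientation_coherence + 0.02)
      thetas <- (mu + 0.5 * rvonmises(n_fil, 0, kappa)) %% pi
      ds <- 0.7
      xs_all <- vector("list", n_fil)
      ys_all <- vector("list", n_fil)
      ws_all <- vector("list", n_fil)
      for (f in seq_len(n_fil)) {
        L <- stats::runif(1, 0.35, 0.75) * min(H, W)
        n_steps <- max(8L, ceiling(L / ds))
        th <- thetas[f] + cumsum(stats::rnorm(n_steps, 0, 0.015)) +
          sample(c(0, pi), 1)
        xs <- stats::runif(1, 1, W) + cumsum(cos(th)) * ds
        ys <- stats::runif(1, 1, H) + cumsum(sin(th)) * ds
        s <- seq_len(n_steps) * ds
        amp <- stats::runif(1, 0.6, 1.0)
        phase <- stats::runif(1, 0, 2 * pi)
        inten <- amp * (1 - p$bead_contrast *
                          (0.5 + 0.5 * sin(2 * pi * s / p$bead_spacing +
                                           phase)))
        if (stats::runif(1) < p$fragmentation) {
          n_gap <- 1L + stats::rpois(1, 2)
          gap_c <- stats::runif(n_gap, 0, max(s))
          gap_w <- stats::runif(n_gap, 0.04, 0.12) * max(s)
          keep <- rep(TRUE, n_steps)
          for (g in seq_len(n_gap)) {
            keep <- keep & (abs(s - gap_c[g]) > gap_w[g] / 2)
          }
          xs <- xs[keep]; ys <- ys[keep]; inten <- inten[keep]
        }
        xs_all[[f]] <- xs; ys_all[[f]] <- ys
        ws_all[[f]] <- 0.62 * inten
      }
      sig <- splat(sig, unlist(xs_all), unlist(ys_all), unlist(ws_all))
    }

    n_punc <- stats::rpois(1, p$puncta_rate * area)
    if (n_punc > 0) {
      sig <- splat(sig,
                   stats::runif(n_punc, 1, W), stats::runif(n_punc, 1, H),
                   1.6 * stats::runif(n_punc, 0.7, 1.3))
    }

    sig <- tanh(blur2d(sig, .render_psf))

    # site physics: background -> blur -> gain -> noise -> clip; blur is
    # linear and the background constant, so the signal is blurred once and
    # channels assembled afterwards
    sigb <- blur2d(sig, site$blur_sigma)
    img <- array(0, dim = c(H, W, 3))
    for (ch in 1:3) {
      img[, , ch] <- (site$background_level + .bleed[ch] * sigb) *
        site$brightness_gain
    }
    if (site$noise_sd > 0) {
      img <- img + stats::rnorm(length(img), 0, site$noise_sd)
    }
    img[img < 0] <- 0
    img[img > 1] <- 1
    img
  })
}
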