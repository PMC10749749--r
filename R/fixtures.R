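# Seed handling for the generators: a non-NULL seed gives bit-reproducible
# output and the caller's RNG state is restored afterwards.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Periodic Gaussian blur via the Fourier transfer function
# exp(-2 pi^2 sigma^2 |f|^2), f in cycles/px. Exact for the periodic
# boundary, which keeps spectra of synthetic scenes free of edge artefacts.
fourier_gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  n <- nrow(m); w <- ncol(m)
  fy <- (0:(n - 1)) / n; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (0:(w - 1)) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  H <- exp(-2 * pi^2 * sigma^2 * outer(fy^2, fx^2, "+"))
  Re(stats::fft(stats::fft(m) * H, inverse = TRUE)) / (n * w)
}

# Hard isotropic low-pass: zero all Fourier samples beyond `limit`
# cycles/px.
band_limit_filter <- function(m, limit) {
  n <- nrow(m); w <- ncol(m)
  fy <- (0:(n - 1)) / n; fy[fy > 0.5] <- fy[fy > 0.5] - 1
  fx <- (0:(w - 1)) / w; fx[fx > 0.5] <- fx[fx > 0.5] - 1
  keep <- sqrt(outer(fy^2, fx^2, "+")) <= limit + 1e-12
  Re(stats::fft(stats::fft(m) * keep, inverse = TRUE)) / (n * w)
}

# Ground-truth scene: texture -> optional hard band limit -> Gaussian blur,
# shifted to be non-negative and scaled to the requested amplitude.
make_scene <- function(size = 256, texture = c("filtered_noise",
                                               "white_noise",
                                               "sparse_spots"),
                       blur_sigma = 0, band_limit = NULL, amplitude = 1000) {
  texture <- match.arg(texture)
  m <- switch(texture,
    white_noise = matrix(stats::rnorm(size * size), size, size),
    filtered_noise = fourier_gaussian_blur(
      matrix(stats::rnorm(size * size), size, size), 1.5),
    sparse_spots = {
      s <- matrix(0, size, size)
      n_spots <- max(3L, size^2 %/% 400L)
      iy <- sample.int(size, n_spots, replace = TRUE)
      ix <- sample.int(size, n_spots, replace = TRUE)
      s[cbind(iy, ix)] <- stats::runif(n_spots, 0.5, 1)
      fourier_gaussian_blur(s, 1.2)
    })
  if (!is.null(band_limit)) {
    if (band_limit > 0.5) stop("band_limit must be <= 0.5 cycles/px")
    m <- band_limit_filter(m, band_limit)
  }
  if (blur_sigma > 0) m <- fourier_gaussian_blur(m, blur_sigma)
  m <- m - min(m)
  if (max(m) > 0) m <- m * (amplitude / max(m))
  m
}

add_noise <- function(m, gaussian_sd = 0, poisson = FALSE) {
  if (poisson) m <- matrix(stats::rpois(length(m), pmax(m, 0)),
                           nrow(m), ncol(m))
  if (gaussian_sd > 0)
    m <- pmax(m + stats::rnorm(length(m), sd = gaussian_sd), 0)
  m
}

#' Generate a pair of noisy images of one shared scene
#'
#' Builds a ground-truth scene (texture, optional hard band limit, optional
#' Gaussian blur) and returns two images that share the signal but carry
#' independent noise realizations — the standard input for two-image FRC.
#' With zero noise the two images are identical.
#'
#' @param size image side in pixels.
#' @param seed integer seed; the same seed gives bit-identical output.
#' @param texture `"filtered_noise"` (default; a smooth random field),
#'   `"white_noise"`, or `"sparse_spots"`.
#' @param blur_sigma Gaussian blur sigma applied to the scene, in pixels.
#' @param band_limit hard isotropic low-pass of the scene in cycles/pixel
#'   (<= 0.5), or `NULL` for none.
#' @param gaussian_sd additive Gaussian noise SD (intensity units).
#' @param poisson apply Poisson (shot) noise to the scene intensities.
#' @param amplitude peak intensity of the ground-truth scene.
#' @param pixel_size lateral pixel size in micrometres.
#' @return list with `img1`, `img2` ([image_plane]s) and `scene` (the
#'   noise-free ground truth matrix).
#' @export
make_pair <- function(size = 256, seed = NULL, texture = "filtered_noise",
                      blur_sigma = 0, band_limit = NULL, gaussian_sd = 0,
                      poisson = FALSE, amplitude = 1000, pixel_size = 0.1) {
  with_seed(seed, {
    scene <- make_scene(size, texture, blur_sigma, band_limit, amplitude)
    i1 <- add_noise(scene, gaussian_sd, poisson)
    i2 <- add_noise(scene, gaussian_sd, poisson)
    list(img1 = image_plane(i1, pixel_size),
         img2 = image_plane(i2, pixel_size),
         scene = scene)
  })
}

#' Generate a depth-degrading synthetic Z-stack
#'
#' Emulates the depth dependence of image quality in scattering tissue:
#' slice z is a fresh scene blurred with `sigma_of_z(z)` pixels and scaled
#' by `exp(-depth / intensity_decay_length)`, plus per-slice noise. With an
#' optional registered partner stack the scenes (not the noise) are shared,
#' for two-image FRC.
#'
#' FRC estimates the highest spatial frequency still distinguishable from
#' noise, so depth-dependent blur only registers when images carry a
#' realistic noise floor; the default noise SD of 100 against the default
#' peak of 1000 (PSNR 20 dB) emulates SNR-limited acquisition at depth.
#'
#' @param n_slices number of slices (>= 1).
#' @param size lateral side in pixels.
#' @param sigma_of_z function of the 0-based slice index returning a blur
#'   sigma in pixels, or a numeric vector of length `n_slices`.
#' @param intensity_decay_length 1/e depth of the intensity decay in
#'   micrometres (`Inf` = no decay).
#' @param z_step slice spacing in micrometres.
#' @param gaussian_sd,poisson,texture,amplitude,pixel_size,seed see
#'   [make_pair()].
#' @param pair also generate a partner stack sharing scenes with
#'   independent noise.
#' @return a [z_stack], or (if `pair`) a list `stack`, `partner`.
#' @export
make_depth_stack <- function(n_slices, size = 256,
                             sigma_of_z = function(z) 1 + 0.5 * z,
                             intensity_decay_length = Inf, z_step = 10,
                             gaussian_sd = 100, poisson = FALSE,
                             texture = "filtered_noise", amplitude = 1000,
                             pixel_size = 0.1, seed = NULL, pair = FALSE) {
  if (n_slices < 1L) stop("n_slices must be >= 1")
  sig <- if (is.function(sigma_of_z)) {
    vapply(0:(n_slices - 1L), sigma_of_z, numeric(1))
  } else {
    if (length(sigma_of_z) != n_slices)
      stop("sigma_of_z vector must have length n_slices")
    sigma_of_z
  }
  with_seed(seed, {
    p1 <- vector("list", n_slices)
    p2 <- if (pair) vector("list", n_slices)
    for (z in seq_len(n_slices) - 1L) {
      scale <- exp(-(z * z_step) / intensity_decay_length)
      scene <- make_scene(size, texture, blur_sigma = sig[z + 1L],
                          amplitude = amplitude * scale)
      p1[[z + 1L]] <- image_plane(add_noise(scene, gaussian_sd, poisson),
                                  pixel_size, z)
      if (pair)
        p2[[z + 1L]] <- image_plane(add_noise(scene, gaussian_sd, poisson),
                                    pixel_size, z)
    }
    s1 <- z_stack(p1, z_step)
    if (pair) list(stack = s1, partner = z_stack(p2, z_step)) else s1
  })
}

#' Generate a plane with two regions of different resolution
#'
#' Emulates lateral resolution heterogeneity within one optical section
#' (e.g. differential light scattering across a specimen): the left and
#' right halves of the plane are independent scenes blurred with different
#' sigmas, sharing one noise model. Returns ready-made rectangular ROIs
#' over each half for region-wise mtFRC comparison.
#'
#' @param size plane side in pixels (even).
#' @param sigmas length-2 blur sigmas (px) for the left and right halves.
#' @param seed,texture,gaussian_sd,amplitude,pixel_size see [make_pair()].
#' @return list with `plane` (an [image_plane]), `roi_left`, `roi_right`
#'   (polygon vertex matrices), and `sigmas`.
#' @export
make_heterogeneous_plane <- function(size = 256, sigmas = c(1, 3),
                                     seed = NULL,
                                     texture = "filtered_noise",
                                     gaussian_sd = 100, amplitude = 1000,
                                     pixel_size = 0.1) {
  if (size %% 2L != 0L) stop("`size` must be even")
  with_seed(seed, {
    half <- size %/% 2L
    left <- make_scene(size, texture, blur_sigma = sigmas[1L],
                       amplitude = amplitude)[, seq_len(half)]
    right <- make_scene(size, texture, blur_sigma = sigmas[2L],
                        amplitude = amplitude)[, seq_len(half)]
    m <- add_noise(cbind(left, right), gaussian_sd)
    list(plane = image_plane(m, pixel_size),
         roi_left = cbind(c(0, half, half, 0), c(0, 0, size, size)),
         roi_right = cbind(c(half, size, size, half), c(0, 0, size, size)),
         sigmas = sigmas)
  })
}

#' Generate a synthetic fluorescent-bead stack with ground truth
#'
#' Simulates a field of sub-diffraction beads in a transparent gel imaged
#' with a Gaussian-approximated point spread function. Each bead is an
#' isotropic lateral Gaussian spot of standard deviation
#' `sqrt(psf_sigma^2 + sigma_bead^2)` (the bead itself approximated as a
#' Gaussian whose FWHM equals its diameter), with a Gaussian axial envelope.
#' Bead amplitude decays with depth as `exp(-depth / intensity_decay_length)`
#' (times an optional per-bead jitter); Poisson noise is applied after the
#' decay so the signal-to-noise ratio falls with simulated depth.
#'
#' Defaults mirror a confocal bead acquisition with a 20x/0.7 objective:
#' 210 nm beads, 93.1 nm pixels, 0.5 um z-steps, and a PSF sigma of
#' 0.148 um (the 349 nm Abbe limit at 488 nm divided by 2 sqrt(2 ln 2)).
#'
#' @param n_beads number of beads to place.
#' @param size lateral side in pixels (the default fits 64 beads at the
#'   default separation).
#' @param n_slices number of slices.
#' @param bead_diameter bead diameter in micrometres.
#' @param psf_sigma lateral PSF Gaussian sigma in micrometres.
#' @param axial_sigma axial PSF sigma in micrometres.
#' @param pixel_size lateral pixel size in micrometres.
#' @param z_step slice spacing in micrometres.
#' @param min_separation minimum lateral distance between beads in pixels.
#' @param peak expected photon count at the brightest bead centre.
#' @param background expected background photon count.
#' @param intensity_decay_length 1/e depth of intensity decay in
#'   micrometres (`Inf` = none).
#' @param amplitude_jitter SD of the multiplicative per-bead amplitude
#'   jitter (0 = none).
#' @param poisson apply Poisson noise.
#' @param seed integer seed.
#' @return list with `stack` (a [z_stack]) and `truth` (data frame: `x`,
#'   `y`, `z` 0-based bead centres, `depth_um`, `sigma_um` and `fwhm_um` of
#'   the convolved lateral spot, `amplitude`).
#' @export
make_bead_stack <- function(n_beads = 50, size = 576, n_slices = 41,
                            bead_diameter = 0.21, psf_sigma = 0.148,
                            axial_sigma = 0.5, pixel_size = 0.0931,
                            z_step = 0.5, min_separation = 64, peak = 5000,
                            background = 20,
                            intensity_decay_length = Inf,
                            amplitude_jitter = 0, poisson = TRUE,
                            seed = NULL) {
  cell <- min_separation + 4L
  per_side <- size %/% cell
  if (per_side^2 < n_beads)
    stop("overcrowded request: at most ", per_side^2, " beads fit at this ",
         "separation")
  sigma_bead <- fwhm_to_sigma(bead_diameter)
  sigma_um <- sqrt(psf_sigma^2 + sigma_bead^2)
  sigma_px <- sigma_um / pixel_size
  with_seed(seed, {
    cells <- sample.int(per_side^2, n_beads)
    jit_max <- max((cell - min_separation) / 2 - 1, 0)
    cx <- ((cells - 1L) %% per_side) * cell + cell / 2 +
      stats::runif(n_beads, -jit_max, jit_max)
    cy <- ((cells - 1L) %/% per_side) * cell + cell / 2 +
      stats::runif(n_beads, -jit_max, jit_max)
    margin_z <- max(1L, ceiling(2 * axial_sigma / z_step))
    cz <- if (n_slices > 2L * margin_z) {
      sample(seq(margin_z, n_slices - 1L - margin_z), n_beads,
             replace = TRUE)
    } else {
      rep(n_slices %/% 2L, n_beads)
    }
    depth <- cz * z_step
    amp <- peak * exp(-depth / intensity_decay_length)
    if (amplitude_jitter > 0)
      amp <- amp * pmax(1 + stats::rnorm(n_beads, sd = amplitude_jitter),
                        0.05)
    planes <- lapply(seq_len(n_slices), function(z)
      matrix(background, size, size))
    r <- ceiling(5 * sigma_px)
    sz_ax <- axial_sigma / z_step     # axial sigma in slices
    for (b in seq_len(n_beads)) {
      x <- round(cx[b]); y <- round(cy[b])
      xs <- max(1L, x - r + 1L):min(size, x + r + 1L)
      ys <- max(1L, y - r + 1L):min(size, y + r + 1L)
      lat <- outer(exp(-((ys - 1 - cy[b])^2) / (2 * sigma_px^2)),
                   exp(-((xs - 1 - cx[b])^2) / (2 * sigma_px^2)))
      for (z in seq_len(n_slices) - 1L) {
        ax <- exp(-((z - cz[b])^2) / (2 * sz_ax^2))
        if (ax < 1e-3) next
        planes[[z + 1L]][ys, xs] <- planes[[z + 1L]][ys, xs] +
          amp[b] * ax * lat
      }
    }
    planes <- lapply(seq_len(n_slices), function(z) {
      m <- planes[[z]]
      if (poisson) m <- matrix(stats::rpois(length(m), m), size, size)
      image_plane(m, pixel_size, z - 1L)
    })
    list(stack = z_stack(planes, z_step),
         truth = data.frame(x = cx, y = cy, z = cz, depth_um = depth,
                            sigma_um = sigma_um,
                            fwhm_um = sigma_to_fwhm(sigma_um),
                            amplitude = amp))
  })
}
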