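# Ring-binning geometry is cached per image side: integer Fourier
# frequencies, Euclidean radius rounded to the nearest integer ring, DC
# excluded, rings beyond floor(N/2) (Nyquist) discarded.
.frc_cache <- new.env(parent = emptyenv())

ring_bins <- function(n) {
  key <- as.character(n)
  hit <- .frc_cache[[key]]
  if (!is.null(hit)) return(hit)
  f <- 0:(n - 1L)
  f[f > n / 2] <- f[f > n / 2] - n
  r2 <- outer(f^2, f^2, "+")
  ring <- as.integer(round(sqrt(r2)))
  rmax <- n %/% 2L
  keep <- which(ring >= 1L & ring <= rmax)
  rg <- ring[keep]
  counts <- tabulate(rg, nbins = rmax)
  radii <- which(counts > 0L)
  out <- list(keep = keep, ring = rg, radii = radii,
              counts = counts[radii], rmax = rmax)
  assign(key, out, envir = .frc_cache)
  out
}

# Tukey (tapered cosine) window, alpha = taper fraction.
tukey_window <- function(n, alpha = 0.25) {
  if (alpha <= 0) return(rep(1, n))
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < alpha / 2
  hi <- t > 1 - alpha / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * t[hi] / alpha - 2 / alpha + 1)))
  w
}

# Mean-subtract, optionally window, and zero-pad a raster to the enclosing
# square. Returns a square matrix ready for the FFT.
prep_tile <- function(m, mean_subtract = TRUE, window = FALSE,
                      tukey_alpha = 0.25) {
  if (mean_subtract) m <- m - mean(m)
  if (window)
    m <- m * outer(tukey_window(nrow(m), tukey_alpha),
                   tukey_window(ncol(m), tukey_alpha))
  if (nrow(m) != ncol(m)) {
    n <- max(dim(m))
    sq <- matrix(0, n, n)
    sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
    m <- sq
  }
  m
}

# Core ring correlation on two equally sized square matrices that have
# already been through prep_tile(). Returns per-ring correlations in the
# order of ring_bins(n)$radii; rings with a zero denominator get 0.
frc_rings <- function(m1, m2) {
  n <- nrow(m1)
  b <- ring_bins(n)
  a1 <- stats::fft(m1)[b$keep]
  a2 <- stats::fft(m2)[b$keep]
  s <- rowsum(cbind(Re(a1 * Conj(a2)), Mod(a1)^2, Mod(a2)^2), b$ring)
  den <- sqrt(s[, 2L] * s[, 3L])
  corr <- ifelse(den > 0, s[, 1L] / den, 0)
  as.numeric(corr)
}

#' Fourier ring correlation curve of two images
#'
#' Computes the per-ring correlation between the Fourier transforms of two
#' registered images of the same scene: for each integer ring radius r,
#' `FRC(r) = Re(sum F1 F2*) / sqrt(sum |F1|^2 * sum |F2|^2)` over the
#' Fourier samples whose Euclidean distance from DC rounds to r. The DC term
#' is excluded and rings beyond the Nyquist radius `floor(N/2)` are
#' discarded. Rings where either image has zero energy get correlation 0.
#'
#' Non-square inputs are mean-subtracted and zero-padded to the enclosing
#' square before transforming. Images are mean-subtracted by default so the
#' excluded DC component cannot leak into ring 1; no apodization window is
#' applied by default (a Tukey taper is available for edge-artefact
#' suppression).
#'
#' @param img1,img2 [image_plane] objects (or bare matrices) of identical
#'   shape and pixel size.
#' @param mean_subtract subtract each image's mean before transforming.
#' @param window apply a 2D Tukey window (taper fraction `tukey_alpha`).
#' @param tukey_alpha Tukey taper fraction in (0, 1].
#' @return an object of class `frc_curve` with fields `ring_radii`
#'   (integer ring index, in units of `1/(N * pixel_size)` cycles),
#'   `correlations`, `n_pixels_per_ring`, `image_side` (N after padding)
#'   and `pixel_size` (micrometres).
#' @seealso [frc_resolution()], [single_image_frc()]
#' @export
compute_frc_curve <- function(img1, img2, mean_subtract = TRUE,
                              window = FALSE, tukey_alpha = 0.25) {
  if (inherits(img1, "image_plane")) {
    ps <- img1$pixel_size
    if (inherits(img2, "image_plane") && img2$pixel_size != ps)
      stop("images must share the same pixel size")
    m1 <- img1$pixels
  } else {
    m1 <- img1
    ps <- if (inherits(img2, "image_plane")) img2$pixel_size else 1
  }
  m2 <- if (inherits(img2, "image_plane")) img2$pixels else img2
  if (!identical(dim(m1), dim(m2)))
    stop("images must have identical shape")
  m1 <- prep_tile(m1, mean_subtract, window, tukey_alpha)
  m2 <- prep_tile(m2, mean_subtract, window, tukey_alpha)
  b <- ring_bins(nrow(m1))
  structure(
    list(ring_radii = b$radii,
         correlations = frc_rings(m1, m2),
         n_pixels_per_ring = b$counts,
         image_side = nrow(m1),
         pixel_size = ps),
    class = "frc_curve"
  )
}

#' @export
print.frc_curve <- function(x, ...) {
  cat(sprintf("<frc_curve> N = %d, pixel %g um, %d rings, FRC(1) = %.3f\n",
              x$image_side, x$pixel_size, length(x$ring_radii),
              x$correlations[1L]))
  invisible(x)
}

#' @export
plot.frc_curve <- function(x, cutoff = 1 / 7, ...) {
  freq <- x$ring_radii / (x$image_side * x$pixel_size)
  graphics::plot(freq, x$correlations, type = "l",
                 xlab = "Spatial frequency (cycles/um)", ylab = "FRC", ...)
  graphics::abline(h = cutoff, lty = 2)
  invisible(x)
}

frc_result <- function(resolution, status, crossing_frequency, curve,
                       bounded = FALSE) {
  structure(
    list(resolution = resolution, status = status,
         crossing_frequency = crossing_frequency, curve = curve,
         bounded = bounded),
    class = "frc_result"
  )
}

#' @export
print.frc_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("<frc_result> resolution %.4g um (%.4g cycles/um)%s\n",
                x$resolution, x$crossing_frequency,
                if (isTRUE(x$bounded)) " [bounded]" else ""))
  } else {
    cat(sprintf("<frc_result> %s\n", toupper(x$status)))
  }
  invisible(x)
}

#' Threshold an FRC curve at a fixed cut-off
#'
#' Scans the rings in increasing radius; the first ring whose correlation
#' falls strictly below the cut-off (default the widely used 1/7) defines
#' the crossing frequency `r / (N * pixel_size)` and the resolution is its
#' inverse — the minimum resolvable distance. No interpolation between
#' rings and no curve smoothing is applied. If no ring ever drops below the
#' cut-off the result has status `"no_crossing"`; if the very first ring is
#' already below it the image contains no correlating spatial frequencies
#' and the status is `"no_correlation"`.
#'
#' @param curve an `frc_curve` from [compute_frc_curve()].
#' @param cutoff correlation threshold in (0, 1).
#' @return an object of class `frc_result` with fields `resolution`
#'   (micrometres; `NA` unless status is `"ok"`), `status` (one of `"ok"`,
#'   `"no_crossing"`, `"no_correlation"`), `crossing_frequency`
#'   (cycles/micrometre), `curve`, and `bounded` (see
#'   [single_image_frc()]).
#' @export
frc_resolution <- function(curve, cutoff = 1 / 7) {
  stopifnot(inherits(curve, "frc_curve"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1)
    stop("`cutoff` must be a single number in (0, 1)")
  if (length(curve$correlations) == 0L) stop("empty FRC curve")
  below <- which(curve$correlations < cutoff)
  if (length(below) == 0L)
    return(frc_result(NA_real_, "no_crossing", NA_real_, curve))
  i <- below[1L]
  if (i == 1L)
    return(frc_result(NA_real_, "no_correlation", NA_real_, curve))
  r <- curve$ring_radii[i]
  freq <- r / (curve$image_side * curve$pixel_size)
  frc_result(1 / freq, "ok", freq, curve)
}

#' Split one image into four decimated sub-images
#'
#' Sub-image `(a, b)` (a, b in {0, 1}) collects the pixels at coordinates
#' `(2i + a, 2j + b)`; together the four sub-images tile the original
#' exactly once, and each has twice the pixel size. Odd trailing rows or
#' columns are trimmed (recorded in the `trimmed` attribute).
#'
#' @param img an [image_plane] at least 2 x 2.
#' @return list of four `image_plane`s named `"s00"`, `"s10"`, `"s01"`,
#'   `"s11"` (`s<a><b>` = x-parity a, y-parity b), each with doubled
#'   `pixel_size`.
#' @export
split_single_image <- function(img) {
  stopifnot(inherits(img, "image_plane"))
  m <- img$pixels
  h <- nrow(m); w <- ncol(m)
  if (h < 2L || w < 2L) stop("image must be at least 2x2 to split")
  trimmed <- c(y = h %% 2L, x = w %% 2L)
  h <- h - h %% 2L; w <- w - w %% 2L
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  sub <- function(a, b)  # a = x parity, b = y parity (0-based)
    image_plane(m[seq(1L + b, h, 2L), seq(1L + a, w, 2L), drop = FALSE],
                pixel_size = img$pixel_size * 2, z_index = img$z_index)
  out <- list(s00 = sub(0L, 0L), s10 = sub(1L, 0L),
              s01 = sub(0L, 1L), s11 = sub(1L, 1L))
  attr(out, "trimmed") <- trimmed
  out
}

#' Single-image FRC by four-way sub-sampling
#'
#' Avoids the need for a second registered acquisition: the image is split
#' into four decimated sub-images ([split_single_image()]), FRC is computed
#' for the two diagonal pairs (`s00`/`s11` and `s10`/`s01`, which share
#' identical geometric offsets along both axes), and the reported
#' resolution is the arithmetic mean of the two pair resolutions, evaluated
#' at the doubled sub-image pixel size.
#'
#' Censoring rules: if either pair has no correlating spatial frequencies
#' the result is `"no_correlation"`; if a pair never crosses the cut-off its
#' contribution is replaced by the sub-image Nyquist bound
#' `2 * (2 * pixel_size)` and the result is flagged `bounded = TRUE` (the
#' true resolution is at least as fine as the reported value).
#'
#' @param img an [image_plane], at least 4 x 4.
#' @param cutoff correlation threshold in (0, 1).
#' @param average_curves average the two pair curves point-wise and
#'   threshold once, instead of averaging the two pair resolutions.
#' @inheritParams compute_frc_curve
#' @return an `frc_result`; `pair_results` holds the two per-pair results.
#' @export
single_image_frc <- function(img, cutoff = 1 / 7, average_curves = FALSE,
                             mean_subtract = TRUE, window = FALSE,
                             tukey_alpha = 0.25) {
  stopifnot(inherits(img, "image_plane"))
  if (nrow(img$pixels) < 4L || ncol(img$pixels) < 4L)
    stop("image must be at least 4x4 for single-image FRC")
  s <- split_single_image(img)
  c1 <- compute_frc_curve(s$s00, s$s11, mean_subtract, window, tukey_alpha)
  c2 <- compute_frc_curve(s$s10, s$s01, mean_subtract, window, tukey_alpha)
  if (average_curves) {
    avg <- c1
    avg$correlations <- (c1$correlations + c2$correlations) / 2
    return(frc_resolution(avg, cutoff))
  }
  r1 <- frc_resolution(c1, cutoff)
  r2 <- frc_resolution(c2, cutoff)
  pair <- list(r1, r2)
  if (r1$status == "no_correlation" || r2$status == "no_correlation") {
    out <- frc_result(NA_real_, "no_correlation", NA_real_, c1)
    out$pair_results <- pair
    return(out)
  }
  sub_ps <- s$s00$pixel_size           # = 2 * original pixel size
  nyquist_bound <- 2 * sub_ps
  vals <- vapply(pair, function(r)
    if (r$status == "ok") r$resolution else nyquist_bound, numeric(1))
  bounded <- any(vapply(pair, function(r) r$status == "no_crossing",
                        logical(1)))
  out <- frc_result(mean(vals), "ok", 1 / mean(vals), c1, bounded = bounded)
  out$pair_results <- pair
  out
}

#' Two-image FRC resolution
#'
#' Convenience wrapper: [compute_frc_curve()] followed by
#' [frc_resolution()].
#'
#' @inheritParams compute_frc_curve
#' @inheritParams frc_resolution
#' @return an `frc_result`.
#' @export
two_image_frc <- function(img1, img2, cutoff = 1 / 7, mean_subtract = TRUE,
                          window = FALSE, tukey_alpha = 0.25) {
  frc_resolution(
    compute_frc_curve(img1, img2, mean_subtract, window, tukey_alpha),
    cutoff)
}

#' Abbe diffraction limit and Nyquist pixel size
#'
#' `abbe_resolution()` returns the minimum theoretically resolvable
#' distance `d = lambda / (2 NA)`, reported to the nearest nanometre.
#' `nyquist_pixel_size()` returns the pixel size required by
#' Shannon–Nyquist sampling, half the resolvable distance.
#'
#' @param wavelength excitation/emission wavelength in nanometres (> 0).
#' @param numerical_aperture objective numerical aperture in (0, 1.7].
#' @return `abbe_resolution()`: the Abbe limit `d` in nanometres (nearest
#'   nm); `nyquist_pixel_size()`: `d / 2` in nanometres.
#' @examples
#' abbe_resolution(488, 0.7)   # 349 nm (confocal, 20x/0.7)
#' abbe_resolution(920, 0.7)   # 657 nm (two-photon)
#' nyquist_pixel_size(abbe_resolution(488, 0.7))
#' @export
abbe_resolution <- function(wavelength, numerical_aperture) {
  if (!is.numeric(wavelength) || any(wavelength <= 0))
    stop("`wavelength` must be positive (nanometres)")
  if (!is.numeric(numerical_aperture) || any(numerical_aperture <= 0) ||
      any(numerical_aperture > 1.7))
    stop("`numerical_aperture` must be in (0, 1.7]")
  round(wavelength / (2 * numerical_aperture))
}

#' @rdname abbe_resolution
#' @param d resolvable distance in nanometres, e.g. from
#'   `abbe_resolution()`.
#' @export
nyquist_pixel_size <- function(d) {
  if (!is.numeric(d) || any(d <= 0)) stop("`d` must be positive")
  d / 2
}
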