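# Conversion between a Gaussian standard deviation and its full width at
# half maximum: FWHM = 2 * sqrt(2 * ln 2) * sigma.
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert a Gaussian sigma to FWHM (and back)
#'
#' For a Gaussian profile the full width at half maximum is
#' `2 * sqrt(2 * ln 2) * sigma` (about 2.3548 sigma).
#'
#' @param sigma Gaussian standard deviation (any length unit).
#' @return the FWHM in the same unit.
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' @rdname sigma_to_fwhm
#' @param fwhm full width at half maximum.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

#' Extract per-bead substacks from a bead field
#'
#' Candidate beads are pixels brighter than `threshold` times the global
#' maximum that are the brightest pixel within `min_separation` laterally
#' (checked in x and y only, across all slices); where two candidates
#' conflict the brighter one is kept. Each accepted candidate yields a crop
#' of `box_size` x `box_size` pixels laterally and up to `box_size` slices
#' axially, clamped to the stack bounds.
#'
#' @param stack a [z_stack].
#' @param box_size lateral (and maximal axial) substack side in pixels.
#' @param min_separation minimum lateral separation between beads in pixels
#'   (default `box_size`).
#' @param threshold detection threshold as a fraction of the global maximum.
#' @return list of substacks; each is a list with `stack` (a [z_stack] of
#'   the crop), `offset` (0-based `c(x, y, z)` of the crop origin in the
#'   parent), and `seed_peak` (intensity of the detection pixel). May be
#'   empty.
#' @export
extract_bead_substacks <- function(stack, box_size = 64,
                                   min_separation = box_size,
                                   threshold = 0.2) {
  stopifnot(inherits(stack, "z_stack"))
  h <- nrow(stack$planes[[1L]]$pixels)
  w <- ncol(stack$planes[[1L]]$pixels)
  nz <- length(stack)
  gmax <- max(vapply(stack$planes, function(p) max(p$pixels), numeric(1)))
  if (gmax <= 0) return(list())
  thr <- threshold * gmax
  cand <- list()
  for (z in seq_len(nz)) {
    m <- stack$planes[[z]]$pixels
    idx <- which(m > thr)
    if (length(idx) == 0L) next
    cand[[length(cand) + 1L]] <- cbind(
      x = (idx - 1L) %/% h, y = (idx - 1L) %% h, z = z - 1L,
      intensity = m[idx])
  }
  if (length(cand) == 0L) return(list())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand[, "intensity"]), , drop = FALSE]
  keep <- matrix(numeric(0), ncol = 4L)
  for (i in seq_len(nrow(cand))) {
    if (nrow(keep) == 0L ||
        all(sqrt((keep[, 1L] - cand[i, "x"])^2 +
                 (keep[, 2L] - cand[i, "y"])^2) >= min_separation))
      keep <- rbind(keep, cand[i, ])
  }
  lapply(seq_len(nrow(keep)), function(i) {
    cx <- keep[i, 1L]; cy <- keep[i, 2L]; cz <- keep[i, 3L]
    x0 <- min(max(cx - box_size %/% 2L, 0L), max(w - box_size, 0L))
    y0 <- min(max(cy - box_size %/% 2L, 0L), max(h - box_size, 0L))
    z0 <- min(max(cz - box_size %/% 2L, 0L), max(nz - box_size, 0L))
    bs_x <- min(box_size, w); bs_y <- min(box_size, h)
    zs <- (z0 + 1L):min(z0 + box_size, nz)
    planes <- lapply(zs, function(z)
      crop_plane(stack$planes[[z]], x0, y0, bs_x, bs_y))
    list(stack = z_stack(planes, stack$z_step,
                         depth_origin = stack$depth_origin +
                           (zs[1L] - 1L) * stack$z_step),
         offset = c(x = x0, y = y0, z = zs[1L] - 1L),
         seed_peak = unname(keep[i, 4L]))
  })
}

#' Locate a bead centre in a substack
#'
#' Applies a per-plane disc median filter of radius 1 pixel (to suppress
#' single hot pixels) and returns the coordinates of the maximum-intensity
#' pixel; ties are broken by the smallest `(z, y, x)` in lexicographic
#' order.
#'
#' @param substack a [z_stack] (typically from
#'   [extract_bead_substacks()]).
#' @return integer vector `c(x, y, z)` of 0-based coordinates within the
#'   substack.
#' @export
locate_centre <- function(substack) {
  stopifnot(inherits(substack, "z_stack"))
  best <- c(-Inf, NA, NA, NA)
  for (z in seq_along(substack$planes)) {
    f <- disc_median_filter(substack$planes[[z]]$pixels, 1)
    v <- max(f)
    if (v > best[1L]) {
      idx <- which(f == v)          # column-major: smallest (x, then y)
      # lexicographic (z, y, x): smallest y then x within this plane
      ij <- arrayInd(idx, dim(f))
      ord <- order(ij[, 1L], ij[, 2L])
      best <- c(v, ij[ord[1L], 2L] - 1L, ij[ord[1L], 1L] - 1L, z - 1L)
    }
  }
  c(x = as.integer(best[2L]), y = as.integer(best[3L]),
    z = as.integer(best[4L]))
}

# 1D Gaussian-with-offset least-squares fit: a*exp(-(u-mu)^2/(2 s^2)) + c.
# Returns c(sigma, a, mu, c) or NULL on failure.
fit_gaussian_profile <- function(v) {
  u <- seq_along(v) - 1
  rng <- diff(range(v))
  if (rng <= 0) return(NULL)
  a0 <- max(v) - min(v); c0 <- min(v); mu0 <- u[which.max(v)]
  wts <- pmax(v - c0, 0)
  s0 <- sqrt(sum(wts * (u - mu0)^2) / sum(wts))
  if (!is.finite(s0) || s0 <= 0) s0 <- length(v) / 6
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ a * exp(-(u - mu)^2 / (2 * s^2)) + c,
      start = list(a = a0, mu = mu0, s = s0, c = c0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  p <- stats::coef(fit)
  if (!is.finite(p[["s"]]) || abs(p[["s"]]) <= 0 || p[["a"]] <= 0)
    return(NULL)
  c(sigma = abs(p[["s"]]), a = p[["a"]], mu = p[["mu"]], c = p[["c"]])
}

#' Fit lateral FWHM of a bead
#'
#' Fits a 1D Gaussian with offset, `a * exp(-(u - mu)^2 / (2 sigma^2)) + c`,
#' to the horizontal and vertical intensity profiles through the bead
#' centre, and converts each fitted sigma to a full width at half maximum
#' via `FWHM = 2 sqrt(2 ln 2) sigma`. The final FWHM is the mean of the X
#' and Y values, in micrometres. Profiles are read from the raw (unfiltered)
#' plane of the centre slice; the median filter used for centre finding
#' would bias the width of near-Nyquist spots.
#'
#' @param substack a [z_stack] containing one bead.
#' @param centre 0-based `c(x, y, z)` centre, e.g. from [locate_centre()].
#' @return list with `fwhm_x`, `fwhm_y`, `fwhm`, `sigma_x`, `sigma_y` (all
#'   micrometres) and `ok`; on fit failure `ok = FALSE` and the values are
#'   `NA` (such records are excluded from summaries).
#' @export
fit_fwhm <- function(substack, centre) {
  stopifnot(inherits(substack, "z_stack"))
  plane <- substack$planes[[centre[[3L]] + 1L]]
  m <- plane$pixels
  row_prof <- m[centre[[2L]] + 1L, ]   # horizontal (along x)
  col_prof <- m[, centre[[1L]] + 1L]   # vertical (along y)
  if (length(row_prof) < 7L || length(col_prof) < 7L)
    stop("profile lines need at least 7 samples")
  fx <- fit_gaussian_profile(row_prof)
  fy <- fit_gaussian_profile(col_prof)
  if (is.null(fx) || is.null(fy))
    return(list(fwhm_x = NA_real_, fwhm_y = NA_real_, fwhm = NA_real_,
                sigma_x = NA_real_, sigma_y = NA_real_, ok = FALSE))
  ps <- plane$pixel_size
  sx <- fx[["sigma"]] * ps; sy <- fy[["sigma"]] * ps
  list(fwhm_x = sigma_to_fwhm(sx), fwhm_y = sigma_to_fwhm(sy),
       fwhm = (sigma_to_fwhm(sx) + sigma_to_fwhm(sy)) / 2,
       sigma_x = sx, sigma_y = sy, ok = TRUE)
}

#' Single-image FRC of a bead
#'
#' Extracts a square tile (default 64 x 64 px, i.e. 32 x 32 px sub-images)
#' centred on the bead from the raw intensities of the centre's z-plane —
#' clamped inward near edges — and applies single-image FRC.
#'
#' @param substack a [z_stack] containing one bead.
#' @param centre 0-based `c(x, y, z)` centre within the substack.
#' @param tile tile side in pixels.
#' @param cutoff FRC threshold.
#' @return an `frc_result`.
#' @export
bead_frc <- function(substack, centre, tile = 64, cutoff = 1 / 7) {
  stopifnot(inherits(substack, "z_stack"))
  plane <- substack$planes[[centre[[3L]] + 1L]]
  h <- nrow(plane$pixels); w <- ncol(plane$pixels)
  tile <- min(tile, h, w)
  x0 <- min(max(centre[[1L]] - tile %/% 2L, 0L), w - tile)
  y0 <- min(max(centre[[2L]] - tile %/% 2L, 0L), h - tile)
  single_image_frc(crop_plane(plane, x0, y0, tile), cutoff = cutoff)
}

#' Analyse every bead in a stack
#'
#' Full bead workflow: extract substacks, locate centres, fit lateral
#' FWHM, compute per-bead single-image FRC, and record peak intensities
#' (raw = median-filtered maximum, normalised to the brightest bead).
#'
#' @inheritParams extract_bead_substacks
#' @param tile FRC tile side in pixels.
#' @param cutoff FRC threshold.
#' @return data frame of class `bead_table` with one row per bead: `x`,
#'   `y`, `z` (0-based stack coordinates of the centre), `depth_um`,
#'   `fwhm_x_um`, `fwhm_y_um`, `fwhm_um`, `sigma_x_um`, `sigma_y_um`,
#'   `frc_um`, `frc_status`, `peak_raw`, `peak_norm`, `flags`.
#' @export
analyze_beads <- function(stack, box_size = 64, min_separation = box_size,
                          threshold = 0.2, tile = 64, cutoff = 1 / 7) {
  subs <- extract_bead_substacks(stack, box_size, min_separation, threshold)
  if (length(subs) == 0L)
    return(structure(data.frame(), class = c("bead_table", "data.frame")))
  rows <- lapply(subs, function(s) {
    ctr <- locate_centre(s$stack)
    fil <- disc_median_filter(s$stack$planes[[ctr[[3L]] + 1L]]$pixels, 1)
    peak <- fil[ctr[[2L]] + 1L, ctr[[1L]] + 1L]
    fw <- fit_fwhm(s$stack, ctr)
    fr <- bead_frc(s$stack, ctr, tile = tile, cutoff = cutoff)
    gz <- s$offset[[3L]] + ctr[[3L]]
    data.frame(
      x = s$offset[[1L]] + ctr[[1L]], y = s$offset[[2L]] + ctr[[2L]],
      z = gz, depth_um = stack$depth_origin + gz * stack$z_step,
      fwhm_x_um = fw$fwhm_x, fwhm_y_um = fw$fwhm_y, fwhm_um = fw$fwhm,
      sigma_x_um = fw$sigma_x, sigma_y_um = fw$sigma_y,
      frc_um = fr$resolution, frc_status = fr$status,
      peak_raw = peak, peak_norm = NA_real_,
      flags = if (fw$ok) "" else "fwhm_fit_failed")
  })
  out <- do.call(rbind, rows)
  out$peak_norm <- out$peak_raw / max(out$peak_raw)
  class(out) <- c("bead_table", "data.frame")
  out
}

#' Summarise a bead table
#'
#' Produces the regression summaries of the bead validation workflow:
#' linear fits of FWHM vs depth, FRC vs depth and FRC vs FWHM (slope,
#' intercept, Pearson r and slope standard error), an exponential decay fit
#' `I(z) = A exp(-z / l)` of normalised peak intensity vs depth, and the
#' paired percentage difference between FRC and FWHM per bead,
#' `(FRC - FWHM) / FWHM * 100` (mean and SD). Records with failed FWHM fits
#' or undefined FRC are excluded from the fits that need them.
#'
#' @param records a `bead_table` from [analyze_beads()].
#' @return object of class `bead_summary`: list with `records`, `fits`
#'   (named list of linear fits), `decay` (list `A`, `length_um`), and
#'   `frc_vs_fwhm_pct` (list `mean`, `sd`, `n`).
#' @export
bead_summary <- function(records) {
  if (!is.data.frame(records) || nrow(records) < 2L)
    stop("need at least 2 bead records")
  lin <- function(x, y) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 2L) return(NULL)
    fit <- stats::lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
    co <- summary(fit)$coefficients
    list(slope = co["x", "Estimate"], intercept = co["(Intercept)",
                                                     "Estimate"],
         slope_se = co["x", "Std. Error"],
         r = if (stats::sd(y[ok]) > 0 && stats::sd(x[ok]) > 0)
           stats::cor(x[ok], y[ok]) else NA_real_,
         n = sum(ok))
  }
  fits <- list(
    fwhm_vs_depth = lin(records$depth_um, records$fwhm_um),
    frc_vs_depth = lin(records$depth_um, records$frc_um),
    frc_vs_fwhm = lin(records$fwhm_um, records$frc_um))
  ok <- is.finite(records$peak_norm) & is.finite(records$depth_um)
  decay <- NULL
  if (sum(ok) >= 3L && stats::sd(records$depth_um[ok]) > 0) {
    df <- data.frame(z = records$depth_um[ok], i = records$peak_norm[ok])
    # on decay-free data the length estimate diverges and the optimizer
    # stops at maxiter; the (huge) estimate is still meaningful
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        i ~ A * exp(-z / l), data = df,
        start = list(A = max(df$i), l = max(max(df$z), 1) / 2),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      p <- stats::coef(fit)
      decay <- list(A = p[["A"]], length_um = p[["l"]])
    }
  }
  both <- is.finite(records$frc_um) & is.finite(records$fwhm_um) &
    records$fwhm_um > 0
  pct <- (records$frc_um[both] - records$fwhm_um[both]) /
    records$fwhm_um[both] * 100
  structure(
    list(records = records, fits = fits, decay = decay,
         frc_vs_fwhm_pct = list(
           mean = if (length(pct)) mean(pct) else NA_real_,
           sd = if (length(pct) > 1L) stats::sd(pct) else NA_real_,
           n = length(pct))),
    class = "bead_summary")
}

#' @export
print.bead_summary <- function(x, ...) {
  cat(sprintf("Bead validation summary (%d beads)\n", nrow(x$records)))
  for (nm in names(x$fits)) {
    f <- x$fits[[nm]]
    if (is.null(f)) next
    cat(sprintf("  %-14s slope %.4g (se %.3g), intercept %.4g, r %.3f (n=%d)\n",
                nm, f$slope, f$slope_se, f$intercept, f$r, f$n))
  }
  if (!is.null(x$decay))
    cat(sprintf("  intensity decay: I(z) = %.3g * exp(-z / %.4g um)\n",
                x$decay$A, x$decay$length_um))
  p <- x$frc_vs_fwhm_pct
  if (is.finite(p$mean))
    cat(sprintf("  FRC vs FWHM: mean diff %.2f%%, sd %.2f%% (n=%d)\n",
                p$mean, p$sd, p$n))
  invisible(x)
}

#' Write a per-bead CSV report
#'
#' @param records a `bead_table`.
#' @param path output CSV path.
#' @return (invisibly) the path.
#' @export
write_bead_csv <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("empty bead table")
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
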