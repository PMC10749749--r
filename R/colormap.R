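#' Rolling-block FRC resolution map
#'
#' Builds a high-detail resolution map: for every pixel inside the ROI a
#' square block centred on that pixel is evaluated with FRC and the
#' resulting resolution is stored at the pixel. Near the image border the
#' block is clamped inward (the centre pixel is kept, the block shifted)
#' rather than zero-padded, which avoids injecting artificially sharp edges
#' that would distort the estimate. Pixels whose block contains no
#' correlating spatial frequencies are left undefined (`NA`), as are pixels
#' outside the ROI.
#'
#' At `stride = 1` (the default) this costs one FRC evaluation per ROI
#' pixel — a full w x h ROI costs w*h evaluations. `stride > 1` evaluates
#' on a coarser lattice and fills the remaining ROI pixels from the nearest
#' evaluated site.
#'
#' @param plane an [image_plane].
#' @param polygons list of ROI polygon vertex matrices.
#' @param block_size block side in pixels (default 64); must fit in the
#'   image.
#' @param cutoff FRC threshold.
#' @param mode `"single"` or `"pair"` (with `partner`).
#' @param partner registered second [image_plane] for `mode = "pair"`.
#' @param stride evaluate every `stride`-th pixel along each axis.
#' @param frc_fun optional replacement evaluation function with signature
#'   `function(plane, partner, x0, y0, block_size)` returning a resolution
#'   in micrometres or `NA`; used for instrumentation (e.g. counting
#'   evaluations) and testing.
#' @param ... passed to the FRC engines.
#' @return an object of class `resolution_map`: list with `values` (numeric
#'   matrix aligned to the plane, `NA` where undefined), `block_size`,
#'   `pixel_size`, `n_evaluations`.
#' @export
rolling_frc_map <- function(plane, polygons, block_size = 64,
                            cutoff = 1 / 7, mode = c("single", "pair"),
                            partner = NULL, stride = 1L, frc_fun = NULL,
                            ...) {
  stopifnot(inherits(plane, "image_plane"))
  mode <- match.arg(mode)
  h <- nrow(plane$pixels); w <- ncol(plane$pixels)
  if (block_size > min(h, w))
    stop("block larger than image")
  if (mode == "pair" && is.null(partner))
    stop("mode = \"pair\" requires a partner plane")
  if (is.null(frc_fun))
    frc_fun <- function(plane, partner, x0, y0, block_size) {
      r <- tile_frc(plane, partner, x0, y0, block_size, cutoff, mode, ...)
      if (r$status == "no_correlation") NA_real_ else r$resolution
    }
  mask <- polygon_mask(w, h, polygons)
  values <- matrix(NA_real_, h, w)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(structure(list(values = values, block_size = block_size,
                          pixel_size = plane$pixel_size, n_evaluations = 0L),
                     class = "resolution_map"))
  xs <- unname(idx[, 2L]) - 1L; ys <- unname(idx[, 1L]) - 1L  # 0-based
  stride <- max(1L, as.integer(stride))
  if (stride > 1L) {
    on_lattice <- (xs %% stride == 0L) & (ys %% stride == 0L)
    ex <- xs[on_lattice]; ey <- ys[on_lattice]
    if (length(ex) == 0L) { ex <- xs[1L]; ey <- ys[1L] }
  } else {
    ex <- xs; ey <- ys
  }
  half <- block_size %/% 2L
  # clamp block origins so the block stays inside the image
  ox <- pmin(pmax(ex - half, 0L), w - block_size)
  oy <- pmin(pmax(ey - half, 0L), h - block_size)
  n_eval <- length(ex)
  vals <- numeric(n_eval)
  for (i in seq_len(n_eval))
    vals[i] <- frc_fun(plane, partner, ox[i], oy[i], block_size)
  if (stride == 1L) {
    values[cbind(ey + 1L, ex + 1L)] <- vals
  } else {
    # nearest evaluated lattice site for every ROI pixel
    nx <- round(xs / stride) * stride
    ny <- round(ys / stride) * stride
    pos <- match(paste(nx, ny), paste(ex, ey))
    near <- rep(NA_real_, length(xs))
    hit <- !is.na(pos)
    near[hit] <- vals[pos[hit]]
    for (j in which(!hit)) {  # closest site by Euclidean distance
      d2 <- (ex - xs[j])^2 + (ey - ys[j])^2
      near[j] <- vals[which.min(d2)]
    }
    values[cbind(ys + 1L, xs + 1L)] <- near
  }
  structure(list(values = values, block_size = as.integer(block_size),
                 pixel_size = plane$pixel_size,
                 n_evaluations = n_eval),
            class = "resolution_map")
}

#' @export
print.resolution_map <- function(x, ...) {
  def <- sum(!is.na(x$values))
  cat(sprintf(
    "<resolution_map> %d x %d px, block %d, %d defined px (%d evaluations)\n",
    ncol(x$values), nrow(x$values), x$block_size, def, x$n_evaluations))
  if (def > 0)
    cat(sprintf("  values: %.3g-%.3g um (median %.3g)\n",
                min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE),
                stats::median(x$values, na.rm = TRUE)))
  invisible(x)
}

# NA-aware disc median filter shared by the colourmap smoother and the bead
# centre finder. Pixels that are NA on input stay NA; the median at a
# defined pixel is taken over the defined pixels of its disc neighbourhood
# (dx^2 + dy^2 <= radius^2), clipped at the borders.
disc_median_filter <- function(m, radius) {
  if (radius <= 0) return(m)
  if (radius <= 1 && !anyNA(m) && nrow(m) > 4L && ncol(m) > 4L)
    return(disc_median_filter_r1(m))
  disc_median_filter_generic(m, radius)
}

disc_median_filter_generic <- function(m, radius, rows = NULL,
                                       cols = NULL) {
  r <- as.integer(ceiling(radius))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= radius^2 + 1e-9, ]
  h <- nrow(m); w <- ncol(m)
  if (is.null(rows)) rows <- seq_len(h)
  if (is.null(cols)) cols <- seq_len(w)
  big <- matrix(NA_real_, h + 2L * r, w + 2L * r)
  big[r + seq_len(h), r + seq_len(w)] <- m
  n <- length(rows) * length(cols)
  stackm <- matrix(NA_real_, n, nrow(off))
  for (k in seq_len(nrow(off))) {
    stackm[, k] <- big[cbind(rep(r + rows + off$dy[k], length(cols)),
                             rep(r + cols + off$dx[k],
                                 each = length(rows)))]
  }
  med <- apply(stackm, 1L, stats::median, na.rm = TRUE)
  out <- matrix(med, length(rows), length(cols))
  out[is.na(m[rows, cols, drop = FALSE])] <- NA_real_
  out[is.nan(out)] <- NA_real_
  out
}

# Fast path for the radius-1 disc (5-point cross) on NA-free input: a
# vectorized median-of-5 sorting network on the interior, generic clipped
# medians on the 1-pixel border band. Identical to the generic path.
disc_median_filter_r1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  ri <- 2:(h - 1L); ci <- 2:(w - 1L)
  v1 <- m[ri, ci]                 # centre
  v2 <- m[ri - 1L, ci]; v3 <- m[ri + 1L, ci]
  v4 <- m[ri, ci - 1L]; v5 <- m[ri, ci + 1L]
  # median-of-5 selection network: sort two pairs, discard the smaller
  # pair-minimum (it cannot be the median), then take the 2nd smallest of
  # the remaining two sorted pairs.
  a <- pmin(v1, v2); b <- pmax(v1, v2)
  c <- pmin(v3, v4); d <- pmax(v3, v4)
  swap <- a > c
  m1 <- pmax(a, c)                 # larger pair-minimum, pair stays intact
  p1 <- ifelse(swap, b, d)         # its partner (>= m1)
  st <- ifelse(swap, d, b)         # partner of the discarded minimum
  q1 <- pmin(st, v5); q2 <- pmax(st, v5)
  med <- pmin(pmax(m1, q1), pmin(p1, q2))
  out <- matrix(NA_real_, h, w)
  out[ri, ci] <- med
  br <- c(1L, h); bc <- c(1L, w)
  out[br, ] <- disc_median_filter_generic(m, 1, rows = br)
  out[, bc] <- disc_median_filter_generic(m, 1, cols = bc)
  out
}

#' Median-smooth a resolution map
#'
#' Smooths block-to-block artefacts with a disc median filter of the given
#' radius (default 10 px, the radius semantics of the Fiji rank filter),
#' computed over defined pixels only; undefined pixels remain undefined and
#' do not pull on their neighbours. Radius 0 is the identity.
#'
#' @param map a `resolution_map`.
#' @param radius disc radius in pixels (>= 0).
#' @return the smoothed `resolution_map`.
#' @export
smooth_map <- function(map, radius = 10) {
  stopifnot(inherits(map, "resolution_map"))
  if (!is.numeric(radius) || length(radius) != 1L || radius < 0)
    stop("`radius` must be a single non-negative number")
  if (radius == 0) return(map)
  map$values <- disc_median_filter(map$values, radius)
  map
}

#' Render a resolution map to an RGB raster
#'
#' Values are clipped to the physical `scale` (micrometres) and mapped
#' through the palette; values above the scale maximum render at the
#' top-of-scale colour (so a `(0, 7)` scale reads "0 to 7+ um"). Undefined
#' pixels get `na_color`.
#'
#' @param map a `resolution_map`.
#' @param scale length-2 numeric `(min, max)` in micrometres, min < max.
#' @param palette vector of colours, low to high; default a perceptually
#'   uniform sequential ramp.
#' @param na_color colour for undefined pixels.
#' @return an `height x width x 3` numeric array of RGB values in [0, 1].
#' @export
render_map <- function(map, scale = c(0, 7),
                       palette = grDevices::hcl.colors(256, "viridis"),
                       na_color = "grey40") {
  stopifnot(inherits(map, "resolution_map"))
  if (length(scale) != 2L || !is.numeric(scale) || scale[1L] >= scale[2L])
    stop("`scale` must be c(min, max) with min < max")
  v <- map$values
  u <- (pmin(pmax(v, scale[1L]), scale[2L]) - scale[1L]) /
    (scale[2L] - scale[1L])
  k <- length(palette)
  bin <- pmin(pmax(as.integer(floor(u * (k - 1))) + 1L, 1L), k)
  cols <- rep(na_color, length(v))
  def <- !is.na(v)
  cols[def] <- palette[bin[def]]
  rgb <- grDevices::col2rgb(cols) / 255
  arr <- array(0, c(nrow(v), ncol(v), 3L))
  arr[, , 1L] <- matrix(rgb[1L, ], nrow(v))
  arr[, , 2L] <- matrix(rgb[2L, ], nrow(v))
  arr[, , 3L] <- matrix(rgb[3L, ], nrow(v))
  arr
}
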