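#' Enumerate ROI-contained tiles on a plane
#'
#' Tiles are laid on a regular non-overlapping grid anchored at the image
#' origin with stride equal to the tile size; tiles straddling the image
#' border are never generated. A tile is selected when at least
#' `containment` of its pixel centres lie inside the ROI (default 1, i.e.
#' the tile must be fully contained within the feature of interest; relax
#' to e.g. 0.5 for thin features).
#'
#' @param plane_shape integer vector `c(height, width)` in pixels (the
#'   `dim()` of an [image_plane]).
#' @param polygons list of polygon vertex matrices (see [polygon_mask()]).
#' @param tile_size tile side in pixels; even and >= 8.
#' @param containment minimum fraction of tile pixel centres inside the ROI.
#' @return integer matrix with columns `x`, `y`: 0-based top-left origins of
#'   the selected tiles, ordered by (y, x).
#' @examples
#' sq <- cbind(c(0, 1024, 1024, 0), c(0, 0, 1024, 1024))
#' nrow(enumerate_tiles(c(1024, 1024), list(sq), 64))  # 16^2 = 256 tiles
#' @export
enumerate_tiles <- function(plane_shape, polygons, tile_size = 64,
                            containment = 1) {
  h <- as.integer(plane_shape[1L]); w <- as.integer(plane_shape[2L])
  if (!is.numeric(tile_size) || length(tile_size) != 1L || tile_size < 8L ||
      tile_size %% 2L != 0L)
    stop("`tile_size` must be a single even integer >= 8")
  tile_size <- as.integer(tile_size)
  if (tile_size > min(h, w))
    stop("tile larger than image (", tile_size, " > ", min(h, w), ")")
  if (containment <= 0 || containment > 1)
    stop("`containment` must be in (0, 1]")
  xs <- seq(0L, w - tile_size, by = tile_size)
  ys <- seq(0L, h - tile_size, by = tile_size)
  if (length(polygons) == 0L)
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("x", "y"))))
  mask <- polygon_mask(w, h, polygons)
  sel <- matrix(FALSE, length(ys), length(xs))
  for (i in seq_along(ys)) for (j in seq_along(xs)) {
    frac <- mean(mask[ys[i] + seq_len(tile_size), xs[j] + seq_len(tile_size)])
    sel[i, j] <- frac >= containment - 1e-12
  }
  idx <- which(sel, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]  # by (y, x)
  cbind(x = xs[idx[, 2L]], y = ys[idx[, 1L]])
}

# Crop a tile (0-based origin) out of a plane.
crop_plane <- function(plane, x0, y0, size_x, size_y = size_x) {
  image_plane(plane$pixels[y0 + seq_len(size_y), x0 + seq_len(size_x),
                           drop = FALSE],
              pixel_size = plane$pixel_size, z_index = plane$z_index)
}

# FRC of one tile in the requested mode.
tile_frc <- function(plane, partner, x0, y0, tile_size, cutoff, mode, ...) {
  t1 <- crop_plane(plane, x0, y0, tile_size)
  if (mode == "single") {
    single_image_frc(t1, cutoff = cutoff, ...)
  } else {
    two_image_frc(t1, crop_plane(partner, x0, y0, tile_size),
                  cutoff = cutoff, ...)
  }
}

#' Mean tiled FRC of one plane
#'
#' Evaluates FRC on every ROI-contained tile of a plane
#' ([enumerate_tiles()]) and aggregates into the plane's mean tiled FRC.
#' Tiles whose FRC curve is below the cut-off from the first ring contain no
#' correlating spatial frequencies (`"no_correlation"`) and are excluded
#' from the mean but counted towards the validity fraction. Tiles are
#' evaluated and summed in fixed (y, x) origin order, so the mean is
#' independent of any caller-side reordering.
#'
#' @param plane an [image_plane].
#' @param polygons list of ROI polygons for this plane (vertex matrices).
#' @param tile_size tile side in pixels.
#' @param cutoff FRC threshold.
#' @param mode `"single"` for single-image FRC on each tile, `"pair"` for
#'   two-image FRC against the registered `partner` plane.
#' @param partner second [image_plane] (required for `mode = "pair"`).
#' @param containment see [enumerate_tiles()].
#' @param ... passed on to the FRC engines (e.g. `window`).
#' @return list with `tiles` (data frame: `x`, `y`, `size`,
#'   `resolution_um`, `status`, `valid`, `bounded`) and `summary` (list:
#'   `mtfrc_um`, `n_tiles`, `n_valid`, `fraction_valid`).
#' @export
mtfrc_plane <- function(plane, polygons, tile_size = 64, cutoff = 1 / 7,
                        mode = c("single", "pair"), partner = NULL,
                        containment = 1, ...) {
  stopifnot(inherits(plane, "image_plane"))
  mode <- match.arg(mode)
  if (mode == "pair") {
    if (is.null(partner)) stop("mode = \"pair\" requires a partner plane")
    if (!identical(dim(plane$pixels), dim(partner$pixels)))
      stop("partner plane shape mismatch")
  }
  org <- enumerate_tiles(dim(plane$pixels), polygons, tile_size, containment)
  n <- nrow(org)
  res <- numeric(n); status <- character(n); bounded <- logical(n)
  for (i in seq_len(n)) {
    r <- tile_frc(plane, partner, org[i, "x"], org[i, "y"], tile_size,
                  cutoff, mode, ...)
    res[i] <- r$resolution
    status[i] <- r$status
    bounded[i] <- isTRUE(r$bounded)
  }
  valid <- status != "no_correlation"
  tiles <- data.frame(x = org[, "x"], y = org[, "y"],
                      size = rep(as.integer(tile_size), n),
                      resolution_um = res, status = status,
                      valid = valid, bounded = bounded)
  n_valid <- sum(valid)
  summary <- list(
    mtfrc_um = if (n_valid > 0) mean(res[valid]) else NA_real_,
    n_tiles = n, n_valid = n_valid,
    fraction_valid = if (n > 0) n_valid / n else NA_real_)
  list(tiles = tiles, summary = summary)
}

#' Mean tiled FRC depth profile of a Z-stack
#'
#' The main entry point of the package. For every slice with a non-empty
#' ROI, the slice is tiled, FRC is evaluated per ROI-contained tile, and the
#' mean tiled FRC (mtFRC) — the mean resolution of the tiles that contain
#' correlating spatial frequencies — is reported against the slice's
#' physical depth. A slice is `reported` when the fraction of valid tiles
#' reaches `validity_threshold` (default 0.95); unreported slices stay in
#' the table but are omitted from the plot.
#'
#' @param stack a [z_stack].
#' @param rois a [roi_set]; slices without an entry contribute no rows.
#' @param tile_size tile side in pixels (default 64).
#' @param cutoff FRC correlation threshold (default 1/7).
#' @param mode `"single"` (single-image FRC, default) or `"pair"`
#'   (two-image FRC against `partner`).
#' @param partner a registered second [z_stack] for `mode = "pair"`.
#' @param validity_threshold minimum fraction of valid tiles for a depth to
#'   be reported (default 0.95).
#' @param containment see [enumerate_tiles()].
#' @param verbose log per-slice tile counts.
#' @param ... passed on to the FRC engines.
#' @return an object of class `mtfrc`: a list with `profile` (data frame:
#'   `z_index`, `depth_um`, `mtfrc_um`, `n_tiles`, `n_valid`,
#'   `fraction_valid`, `reported`), `tiles` (per-slice tile tables),
#'   `params`, and `call`. Methods: `print`, `summary`, `plot`, `coef`
#'   (per-depth mtFRC values), `as.data.frame`.
#' @examples
#' fx <- make_depth_stack(n_slices = 3, size = 128, seed = 1,
#'                        sigma_of_z = function(z) 1 + z)
#' roi <- roi_set(stats::setNames(
#'   rep(list(cbind(c(0, 128, 128, 0), c(0, 0, 128, 128))), 3),
#'   0:2))
#' fit <- mtfrc(fx, roi, tile_size = 64)
#' fit
#' @export
mtfrc <- function(stack, rois, tile_size = 64, cutoff = 1 / 7,
                  mode = c("single", "pair"), partner = NULL,
                  validity_threshold = 0.95, containment = 1,
                  verbose = FALSE, ...) {
  stopifnot(inherits(stack, "z_stack"))
  mode <- match.arg(mode)
  if (!inherits(rois, "roi_set")) stop("`rois` must be a roi_set")
  if (length(rois$polygons) == 0L) stop("empty ROI set")
  if (mode == "pair") {
    if (!inherits(partner, "z_stack"))
      stop("mode = \"pair\" requires a partner z_stack")
    if (length(partner) != length(stack))
      stop("partner stack has a different number of slices")
  }
  d <- dim(stack$planes[[1L]]$pixels)
  rois <- clamp_rois(rois, d[2L], d[1L], length(stack))
  depths <- slice_depths(stack)
  zs <- sort(as.integer(names(rois$polygons)))
  rows <- vector("list", length(zs))
  tile_tables <- vector("list", length(zs))
  names(tile_tables) <- as.character(zs)
  for (k in seq_along(zs)) {
    z <- zs[k]
    polys <- roi_polygons_for_slice(rois, z)
    pr <- mtfrc_plane(stack$planes[[z + 1L]], polys, tile_size, cutoff,
                      mode = mode,
                      partner = if (mode == "pair") partner$planes[[z + 1L]],
                      containment = containment, ...)
    s <- pr$summary
    if (verbose)
      message(sprintf("slice %d (depth %g um): %d tiles, %d valid",
                      z, depths[z + 1L], s$n_tiles, s$n_valid))
    rows[[k]] <- data.frame(
      z_index = z, depth_um = depths[z + 1L], mtfrc_um = s$mtfrc_um,
      n_tiles = s$n_tiles, n_valid = s$n_valid,
      fraction_valid = s$fraction_valid,
      reported = !is.na(s$fraction_valid) &&
        s$fraction_valid >= validity_threshold)
    tile_tables[[k]] <- pr$tiles
  }
  profile <- do.call(rbind, rows)
  structure(
    list(profile = profile, tiles = tile_tables,
         params = list(tile_size = tile_size, cutoff = cutoff, mode = mode,
                       validity_threshold = validity_threshold,
                       containment = containment),
         call = match.call()),
    class = "mtfrc"
  )
}

#' @export
print.mtfrc <- function(x, ...) {
  cat("Mean tiled FRC depth profile\n")
  cat(sprintf("  mode: %s-image FRC, tile %d px, cut-off %.4g, validity >= %g\n",
              x$params$mode, x$params$tile_size, x$params$cutoff,
              x$params$validity_threshold))
  cat(sprintf("  %d depth(s), %d reported\n\n",
              nrow(x$profile), sum(x$profile$reported)))
  print(x$profile, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.mtfrc <- function(object, ...) {
  p <- object$profile
  rep <- p[p$reported, , drop = FALSE]
  out <- list(
    profile = p,
    n_depths = nrow(p),
    n_reported = nrow(rep),
    depth_range_um = range(p$depth_um),
    mtfrc_range_um = if (nrow(rep) > 0) range(rep$mtfrc_um) else c(NA, NA),
    params = object$params)
  class(out) <- "summary.mtfrc"
  out
}

#' @export
print.summary.mtfrc <- function(x, ...) {
  cat(sprintf("mtFRC over %d depths (%g-%g um), %d reported\n",
              x$n_depths, x$depth_range_um[1L], x$depth_range_um[2L],
              x$n_reported))
  if (x$n_reported > 0)
    cat(sprintf("reported mtFRC range: %.4g-%.4g um\n",
                x$mtfrc_range_um[1L], x$mtfrc_range_um[2L]))
  print(x$profile, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.mtfrc <- function(object, ...) {
  stats::setNames(object$profile$mtfrc_um,
                  paste0("depth_", object$profile$depth_um))
}

#' @export
as.data.frame.mtfrc <- function(x, ...) x$profile

#' Plot an mtFRC depth profile
#'
#' Draws mtFRC (micrometres, minimum resolvable distance: lower is better)
#' against depth. Only depths passing the validity rule (`reported`) are
#' drawn.
#'
#' @param x an `mtfrc` object.
#' @param ... further arguments to [graphics::plot()].
#' @return (invisibly) the data frame of rows actually drawn.
#' @export
plot.mtfrc <- function(x, ...) {
  p <- x$profile[x$profile$reported & !is.na(x$profile$mtfrc_um), ,
                 drop = FALSE]
  if (nrow(p) == 0L) {
    graphics::plot(NA, xlim = range(x$profile$depth_um), ylim = c(0, 1),
                   xlab = "Depth (um)", ylab = "mtFRC (um)", ...)
    graphics::text(mean(range(x$profile$depth_um)), 0.5,
                   "no depths pass the validity rule")
  } else {
    graphics::plot(p$depth_um, p$mtfrc_um, type = "b", pch = 19,
                   xlab = "Depth (um)", ylab = "mtFRC (um)", ...)
  }
  invisible(p)
}
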