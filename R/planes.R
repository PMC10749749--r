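#' Construct a single image plane
#'
#' An `image_plane` is one 2D intensity raster together with its physical
#' pixel size. Pixels are stored as a numeric matrix indexed
#' `pixels[y + 1, x + 1]` where `(x, y)` are 0-based image coordinates with
#' x increasing rightwards and y downwards. All user-facing coordinates in
#' this package (ROI vertices, tile origins, bead centres) use this 0-based
#' `(x, y)` convention.
#'
#' @param pixels numeric matrix of finite, non-negative intensities
#'   (rows = y, columns = x).
#' @param pixel_size lateral size of one pixel in micrometres (> 0).
#' @param z_index 0-based slice index of this plane within its stack.
#' @return an object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size, z_index = 0L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1")
  if (!all(is.finite(pixels)))
    stop("intensities must be finite (no NA/NaN/Inf)")
  if (any(pixels < 0))
    stop("intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number (micrometres)")
  storage.mode(pixels) <- "double"
  structure(
    list(pixels = pixels, pixel_size = as.numeric(pixel_size),
         z_index = as.integer(z_index)),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, pixel size %g um, z = %d\n",
              ncol(x$pixels), nrow(x$pixels), x$pixel_size, x$z_index))
  invisible(x)
}

#' @export
dim.image_plane <- function(x) dim(x$pixels)

#' Construct a Z-stack of image planes
#'
#' @param planes list of [image_plane] objects sharing identical width,
#'   height and pixel size. `z_index` fields are (re)assigned 0, 1, ... in
#'   list order.
#' @param z_step axial distance between consecutive planes in micrometres.
#' @param depth_origin physical depth of plane 0 in micrometres.
#' @return an object of class `z_stack`.
#' @export
z_stack <- function(planes, z_step, depth_origin = 0) {
  if (!is.list(planes) || length(planes) < 1L)
    stop("`planes` must be a non-empty list of image_plane objects")
  if (!all(vapply(planes, inherits, logical(1), "image_plane")))
    stop("all elements of `planes` must be image_plane objects")
  d0 <- dim(planes[[1L]]$pixels)
  ps <- planes[[1L]]$pixel_size
  for (p in planes) {
    if (!identical(dim(p$pixels), d0))
      stop("all planes must share the same width and height")
    if (p$pixel_size != ps)
      stop("all planes must share the same pixel size")
  }
  if (!is.numeric(z_step) || length(z_step) != 1L || z_step <= 0)
    stop("`z_step` must be a single positive number (micrometres)")
  for (i in seq_along(planes)) planes[[i]]$z_index <- i - 1L
  structure(
    list(planes = planes, z_step = as.numeric(z_step),
         depth_origin = as.numeric(depth_origin)),
    class = "z_stack"
  )
}

#' @export
print.z_stack <- function(x, ...) {
  d <- dim(x$planes[[1L]]$pixels)
  cat(sprintf(
    "<z_stack> %d slices of %d x %d px, pixel size %g um, z step %g um\n",
    length(x$planes), d[2L], d[1L], x$planes[[1L]]$pixel_size, x$z_step))
  invisible(x)
}

#' @export
length.z_stack <- function(x) length(x$planes)

#' Physical depth of each slice in a stack
#'
#' Depth is the geometric stage depth `depth_origin + z_index * z_step`; no
#' refractive-index correction is applied.
#'
#' @param stack a [z_stack].
#' @return numeric vector of depths in micrometres, one per slice.
#' @export
slice_depths <- function(stack) {
  stopifnot(inherits(stack, "z_stack"))
  stack$depth_origin + (seq_along(stack$planes) - 1) * stack$z_step
}

#' Construct a set of per-slice region-of-interest polygons
#'
#' @param polygons a list whose names are 0-based slice indices (as
#'   characters or coercible integers) and whose elements are lists of
#'   closed polygons; each polygon is an n x 2 numeric matrix of `(x, y)`
#'   vertex coordinates in pixels (0-based). A single polygon matrix may be
#'   given instead of a list of one.
#' @return an object of class `roi_set`.
#' @export
roi_set <- function(polygons) {
  if (!is.list(polygons) || is.null(names(polygons)) ||
      any(names(polygons) == ""))
    stop("`polygons` must be a named list keyed by 0-based slice index")
  z <- suppressWarnings(as.integer(names(polygons)))
  if (any(is.na(z)) || any(z < 0))
    stop("slice keys must be non-negative integers")
  out <- vector("list", length(polygons))
  names(out) <- as.character(z)
  for (i in seq_along(polygons)) {
    polys <- polygons[[i]]
    if (is.matrix(polys)) polys <- list(polys)
    polys <- lapply(polys, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L || !is.numeric(p))
        stop("each polygon must be an n x 2 numeric matrix of (x, y)")
      if (nrow(p) < 3L)
        stop("each polygon needs at least 3 vertices")
      storage.mode(p) <- "double"
      colnames(p) <- c("x", "y")
      p
    })
    out[[i]] <- polys
  }
  structure(list(polygons = out), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  n <- vapply(x$polygons, length, integer(1))
  cat(sprintf("<roi_set> %d slice(s): %s polygon(s) on slices %s\n",
              length(n), paste(n, collapse = ","),
              paste(names(x$polygons), collapse = ",")))
  invisible(x)
}

#' Polygons attached to one slice of an ROI set
#'
#' Slices without an entry have an empty ROI and contribute no tiles.
#'
#' @param rois a [roi_set].
#' @param z_index 0-based slice index.
#' @return list of polygon matrices (possibly empty).
#' @export
roi_polygons_for_slice <- function(rois, z_index) {
  stopifnot(inherits(rois, "roi_set"))
  p <- rois$polygons[[as.character(as.integer(z_index))]]
  if (is.null(p)) list() else p
}

# Clamp polygon vertices into [0, w] x [0, h] and check the stack bounds.
clamp_rois <- function(rois, width, height, n_slices) {
  z <- as.integer(names(rois$polygons))
  if (any(z >= n_slices))
    stop("ROI slice index outside the stack (", max(z), " >= ", n_slices, ")")
  rois$polygons <- lapply(rois$polygons, function(polys)
    lapply(polys, function(p) {
      p[, 1L] <- pmin(pmax(p[, 1L], 0), width)
      p[, 2L] <- pmin(pmax(p[, 2L], 0), height)
      p
    }))
  rois
}

#' Rasterize polygons to a pixel mask
#'
#' A pixel belongs to the ROI if its centre `(x + 0.5, y + 0.5)` lies inside
#' a polygon under the even-odd (ray crossing) rule; multiple polygons on
#' the same slice are combined by union.
#'
#' @param width,height raster size in pixels.
#' @param polygons list of n x 2 `(x, y)` vertex matrices (0-based pixel
#'   coordinates).
#' @return logical matrix (rows = y, columns = x); `TRUE` inside the ROI.
#' @export
polygon_mask <- function(width, height, polygons) {
  mask <- matrix(FALSE, nrow = height, ncol = width)
  if (length(polygons) == 0L) return(mask)
  px <- (seq_len(width) - 1) + 0.5
  py <- (seq_len(height) - 1) + 0.5
  for (poly in polygons) {
    n <- nrow(poly)
    if (n < 3L) stop("polygon needs at least 3 vertices")
    crossings <- matrix(0L, nrow = height, ncol = width)
    xs <- poly[, 1L]; ys <- poly[, 2L]
    xe <- xs[c(2:n, 1L)]; ye <- ys[c(2:n, 1L)]
    for (k in seq_len(n)) {
      y1 <- ys[k]; y2 <- ye[k]
      rows <- which((y1 <= py) != (y2 <= py))
      if (length(rows) == 0L) next
      xint <- xs[k] + (py[rows] - y1) * (xe[k] - xs[k]) / (y2 - y1)
      crossings[rows, ] <- crossings[rows, ] + outer(xint, px, ">")
    }
    mask <- mask | (crossings %% 2L == 1L)
  }
  mask
}
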