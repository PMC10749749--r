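#' Read a multi-page TIFF Z-stack
#'
#' Reads a single-channel multi-page TIFF (8/16-bit integer or 32-bit
#' float samples) into a [z_stack], in file page order. Integer samples are
#' returned at their stored values (not rescaled to [0, 1]) and converted to
#' double precision; multi-channel (RGB or multi-sample) input is rejected.
#'
#' @param path path to the TIFF file.
#' @param pixel_size lateral pixel size in micrometres.
#' @param z_step axial step between pages in micrometres.
#' @param depth_origin physical depth of the first page in micrometres.
#' @return a [z_stack].
#' @export
read_stack <- function(path, pixel_size, z_step, depth_origin = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  planes <- lapply(seq_along(pages), function(i) {
    m <- pages[[i]]
    if (length(dim(m)) != 2L)
      stop("unsupported sample format: multi-channel/RGB TIFF")
    if (!all(is.finite(m)))
      stop("TIFF page ", i, " contains non-finite intensities")
    storage.mode(m) <- "double"
    image_plane(m, pixel_size, i - 1L)
  })
  z_stack(planes, z_step, depth_origin)
}

#' Write a Z-stack as a multi-page TIFF
#'
#' Intensities are stored as unsigned integers (8 or 16 bit) at their raw
#' values, so an integer-valued stack round-trips bit-identically through
#' [read_stack()]. Non-integer or out-of-range intensities are rejected
#' unless `normalize = TRUE`, which (lossily) rescales each stack to the
#' full integer range.
#'
#' @param stack a [z_stack].
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @param normalize rescale intensities to the full integer range.
#' @return (invisibly) the path.
#' @export
write_stack <- function(stack, path, bits = 16, normalize = FALSE) {
  stopifnot(inherits(stack, "z_stack"))
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16")
  top <- 2^bits - 1
  mats <- lapply(stack$planes, function(p) p$pixels)
  if (normalize) {
    mx <- max(vapply(mats, max, numeric(1)))
    if (mx > 0) mats <- lapply(mats, function(m) round(m / mx * top))
  }
  for (m in mats) {
    if (any(m != round(m)) || any(m < 0) || any(m > top))
      stop("intensities must be integers in [0, ", top,
           "] (use normalize = TRUE to rescale)")
  }
  tiff::writeTIFF(lapply(mats, function(m) m / top), path,
                  bits.per.sample = bits)
  invisible(path)
}

# ---- ImageJ .roi binary format -------------------------------------------
# Minimal reader/writer for the ImageJ ROI file format: big-endian, magic
# "Iout", type byte at offset 6, integer bounds at 8..15, vertex count at
# 16, stack position (1-based; 0 = untagged) at 56, and vertex coordinates
# from offset 64 as 16-bit offsets relative to (left, top).
IJ_ROI_TYPES <- c(polygon = 0L, rect = 1L, oval = 2L, line = 3L,
                  freeline = 4L, polyline = 5L, noroi = 6L, freehand = 7L,
                  traced = 8L, angle = 9L, point = 10L)

read_imagej_roi <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64L || rawToChar(raw[1:4]) != "Iout")
    stop("corrupt ImageJ ROI file (bad magic): ", path)
  rd_short <- function(off)  # 0-based offset, big-endian signed short
    readBin(raw[(off + 1):(off + 2)], "integer", size = 2, endian = "big")
  rd_int <- function(off)
    readBin(raw[(off + 1):(off + 4)], "integer", size = 4, endian = "big")
  type <- as.integer(raw[7L])
  top <- rd_short(8L); left <- rd_short(10L)
  bottom <- rd_short(12L); right <- rd_short(14L)
  n <- rd_short(16L)
  position <- rd_int(56L)
  if (type %in% IJ_ROI_TYPES[c("polygon", "freehand")]) {
    if (n < 3L) stop("polygon ROI with fewer than 3 vertices: ", path)
    if (length(raw) < 64L + 4L * n) stop("corrupt ImageJ ROI file: ", path)
    xr <- readBin(raw[65:(64 + 2 * n)], "integer", n = n, size = 2,
                  endian = "big")
    yr <- readBin(raw[(65 + 2 * n):(64 + 4 * n)], "integer", n = n,
                  size = 2, endian = "big")
    poly <- cbind(x = left + xr, y = top + yr)
  } else if (type == IJ_ROI_TYPES[["rect"]]) {
    poly <- cbind(x = c(left, right, right, left),
                  y = c(top, top, bottom, bottom))
  } else if (type == IJ_ROI_TYPES[["oval"]]) {
    # polygon approximation of the inscribed ellipse, 64 vertices
    t <- seq(0, 2 * pi, length.out = 65L)[-65L]
    poly <- cbind(x = (left + right) / 2 + (right - left) / 2 * cos(t),
                  y = (top + bottom) / 2 + (bottom - top) / 2 * sin(t))
  } else {
    nm <- names(IJ_ROI_TYPES)[match(type, IJ_ROI_TYPES)]
    stop("unsupported ImageJ ROI type: ",
         if (is.na(nm)) type else nm,
         " (only polygon, rectangle, oval and freehand are supported)")
  }
  list(polygon = poly, position = position)
}

#' Write a polygon as an ImageJ .roi file
#'
#' Writes a minimal ImageJ ROI file (polygon type) usable for round-trip
#' testing and for handing ROIs back to ImageJ/Fiji.
#'
#' @param polygon n x 2 matrix of `(x, y)` vertices (integer pixels).
#' @param path output path.
#' @param position 1-based stack slice the ROI belongs to; 0 = untagged
#'   (applies to all slices).
#' @return (invisibly) the path.
#' @export
write_imagej_roi <- function(polygon, path, position = 0L) {
  polygon <- round(as.matrix(polygon))
  if (nrow(polygon) < 3L) stop("polygon needs at least 3 vertices")
  x <- as.integer(polygon[, 1L]); y <- as.integer(polygon[, 2L])
  left <- min(x); top <- min(y)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("Iout", con, 4L, eos = NULL)
  wr_short <- function(v) writeBin(as.integer(v), con, size = 2,
                                   endian = "big")
  wr_int <- function(v) writeBin(as.integer(v), con, size = 4,
                                 endian = "big")
  wr_short(228L)                       # version
  writeBin(as.raw(c(IJ_ROI_TYPES[["polygon"]], 0L)), con)
  wr_short(top); wr_short(left)
  wr_short(max(y)); wr_short(max(x))   # bottom, right
  wr_short(nrow(polygon))
  writeBin(raw(56L - 18L), con)        # unused header bytes up to POSITION
  wr_int(position)
  wr_int(0L)                           # header2 offset
  wr_short(x - left)
  wr_short(y - top)
  invisible(path)
}

# ---- plain-text polygon format -------------------------------------------
# One line per slice: "z_index: x1,y1 x2,y2 ..." with 0-based coordinates;
# blank lines and '#' comments are ignored. Repeated z_index lines append
# additional polygons to that slice.

parse_roi_text <- function(lines) {
  polys <- list()
  for (ln in lines) {
    ln <- sub("#.*$", "", ln)
    if (!grepl("\\S", ln)) next
    m <- regmatches(ln, regexec("^\\s*(\\d+)\\s*:\\s*(.*\\S)\\s*$", ln))[[1L]]
    if (length(m) == 0L)
      stop("malformed ROI line: ", trimws(ln))
    z <- m[2L]
    pts <- strsplit(strsplit(m[3L], "\\s+")[[1L]], ",")
    if (any(lengths(pts) != 2L))
      stop("malformed vertex on ROI line for slice ", z)
    poly <- do.call(rbind, lapply(pts, as.numeric))
    if (any(is.na(poly))) stop("non-numeric vertex on slice ", z)
    if (nrow(poly) < 3L)
      stop("polygon on slice ", z, " has fewer than 3 vertices")
    colnames(poly) <- c("x", "y")
    polys[[z]] <- c(polys[[z]], list(poly))
  }
  polys
}

#' Write an ROI set in the plain-text polygon format
#'
#' One line per polygon: `z_index: x1,y1 x2,y2 ...` (0-based pixel
#' coordinates). The format round-trips vertex coordinates exactly through
#' [read_rois()].
#'
#' @param rois a [roi_set].
#' @param path output path.
#' @return (invisibly) the path.
#' @export
write_roi_text <- function(rois, path) {
  stopifnot(inherits(rois, "roi_set"))
  lines <- character(0)
  for (z in names(rois$polygons))
    for (poly in rois$polygons[[z]])
      lines <- c(lines, paste0(z, ": ", paste(
        paste(format(poly[, 1L], trim = TRUE, digits = 15),
              format(poly[, 2L], trim = TRUE, digits = 15), sep = ","),
        collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' Read region-of-interest polygons
#'
#' Reads per-slice ROI polygons from an ImageJ `.roi` file (single ROI), a
#' `.zip` of `.roi` files (multi-slice sets as saved by the ImageJ ROI
#' Manager), or the plain-text polygon format (`z_index: x1,y1 x2,y2 ...`,
#' one line per polygon). Slice assignment for ImageJ ROIs uses the ROI's
#' stack position field when set, else a leading integer in the file name
#' (ROI Manager convention); an untagged single `.roi` applies to every
#' slice of the stack. Vertices are clamped to the image bounds.
#'
#' @param path path to a `.roi`, `.zip`, or text file.
#' @param stack the [z_stack] the ROIs refer to (for bounds and slice
#'   count).
#' @return a [roi_set].
#' @export
read_rois <- function(path, stack) {
  stopifnot(inherits(stack, "z_stack"))
  if (!file.exists(path)) stop("file not found: ", path)
  nz <- length(stack)
  d <- dim(stack$planes[[1L]]$pixels)
  ext <- tolower(tools::file_ext(path))
  broadcast <- function(poly) stats::setNames(
    rep(list(list(poly)), nz), as.character(0:(nz - 1L)))
  add_poly <- function(polys, z, poly) {
    k <- as.character(z)
    polys[[k]] <- c(polys[[k]], list(poly))
    polys
  }
  slice_of <- function(r, fname) {
    if (r$position >= 1L) return(r$position - 1L)
    bn <- basename(fname)
    m <- regmatches(bn, regexpr("^\\d+", bn))
    if (length(m) == 1L && nzchar(m)) return(as.integer(m) - 1L)
    NA_integer_
  }
  if (ext == "roi") {
    r <- read_imagej_roi(path)
    z <- slice_of(r, path)
    polys <- if (is.na(z)) broadcast(r$polygon) else
      add_poly(list(), z, r$polygon)
  } else if (ext == "zip") {
    dir <- tempfile("rois")
    dir.create(dir)
    on.exit(unlink(dir, recursive = TRUE))
    files <- utils::unzip(path, exdir = dir)
    files <- sort(files[grepl("\\.roi$", files, ignore.case = TRUE)])
    if (length(files) == 0L) stop("zip archive contains no .roi files")
    polys <- list()
    for (f in files) {
      r <- read_imagej_roi(f)
      z <- slice_of(r, f)
      if (is.na(z)) {
        for (zz in 0:(nz - 1L)) polys <- add_poly(polys, zz, r$polygon)
      } else {
        polys <- add_poly(polys, z, r$polygon)
      }
    }
  } else {
    polys <- parse_roi_text(readLines(path, warn = FALSE))
  }
  if (length(polys) == 0L) stop("no ROI polygons found in ", path)
  clamp_rois(roi_set(polys), d[2L], d[1L], nz)
}

# ---- result writers ------------------------------------------------------

profile_of <- function(x) {
  if (inherits(x, "mtfrc")) x$profile
  else if (is.data.frame(x)) x
  else stop("expected an mtfrc object or a profile data frame")
}

#' Write an mtFRC depth profile as CSV
#'
#' Columns: `depth_um`, `mtfrc_um`, `n_tiles`, `n_valid`,
#' `fraction_valid`, `reported`. Every computed depth is written, including
#' those that fail the validity rule (`reported = FALSE`).
#'
#' @param profile an `mtfrc` object or its profile data frame.
#' @param path output CSV path.
#' @return (invisibly) the path.
#' @export
write_profile_csv <- function(profile, path) {
  p <- profile_of(profile)
  if (nrow(p) == 0L) stop("empty profile")
  utils::write.csv(
    p[, c("depth_um", "mtfrc_um", "n_tiles", "n_valid", "fraction_valid",
          "reported")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write an mtFRC depth-profile plot
#'
#' Renders mtFRC (micrometres) against depth (micrometres) to a PNG or SVG
#' file; only depths passing the validity rule are drawn (see
#' [plot.mtfrc()]).
#'
#' @param profile an `mtfrc` object or its profile data frame.
#' @param path output path ending in `.png` or `.svg`.
#' @param width,height device size in pixels (PNG) or inches (SVG).
#' @return (invisibly) the data frame of rows drawn.
#' @export
write_profile_plot <- function(profile, path, width = 800, height = 600) {
  p <- profile_of(profile)
  if (nrow(p) == 0L) stop("empty profile")
  obj <- if (inherits(profile, "mtfrc")) profile else
    structure(list(profile = p), class = "mtfrc")
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    grDevices::svg(path, width = width / 100, height = height / 100)
  } else {
    grDevices::png(path, width = width, height = height)
  }
  on.exit(grDevices::dev.off())
  drawn <- plot(obj, main = "mtFRC depth profile")
  invisible(drawn)
}

#' Write a resolution colourmap as PNG
#'
#' Renders the map through [render_map()] — values above the scale maximum
#' are drawn at the top-of-scale colour — and appends a labelled colour bar
#' in physical units (micrometres), with the top tick marked `+` for the
#' clipped range.
#'
#' @param map a `resolution_map`.
#' @param path output PNG path.
#' @param scale physical rendering scale `c(min, max)` in micrometres.
#' @param palette colour ramp, low to high.
#' @param na_color colour for undefined pixels.
#' @return (invisibly) the path.
#' @export
write_colormap_png <- function(map, path, scale = c(0, 7),
                               palette = grDevices::hcl.colors(256,
                                                               "viridis"),
                               na_color = "grey40") {
  arr <- render_map(map, scale, palette, na_color)
  h <- nrow(map$values); w <- ncol(map$values)
  bar_w <- 110L
  grDevices::png(path, width = w + bar_w, height = max(h, 200L))
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1L), widths = c(w, bar_w))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::rasterImage(arr, 0, 0, 1, 1, interpolate = FALSE)
  graphics::par(mar = c(2, 0.5, 2, 3.5))
  ramp <- seq(scale[1L], scale[2L], length.out = length(palette))
  graphics::image(x = 1, y = ramp, z = matrix(seq_along(palette), 1L),
                  col = palette, axes = FALSE, xlab = "", ylab = "")
  ticks <- pretty(scale, 5)
  ticks <- ticks[ticks >= scale[1L] & ticks <= scale[2L]]
  labels <- format(ticks)
  labels[ticks == scale[2L]] <- paste0(format(scale[2L]), "+")
  graphics::axis(4, at = ticks, labels = labels, las = 1)
  graphics::mtext("um", side = 3, line = 0.3, cex = 0.9)
  invisible(path)
}
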