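test_that("rolling map evaluates one block per ROI pixel", {
  pr <- make_pair(size = 96, seed = 51, blur_sigma = 1, gaussian_sd = 100)
  # single-pixel ROI: exactly one evaluation, value = that block's FRC
  px <- cbind(c(40, 41, 41, 40), c(40, 40, 41, 41))
  m <- rolling_frc_map(pr$img1, list(px), block_size = 64)
  expect_equal(m$n_evaluations, 1)
  expect_equal(sum(!is.na(m$values)), 1)
  direct <- single_image_frc(
    image_plane(pr$img1$pixels[9:72, 9:72], 0.1))$resolution
  expect_equal(m$values[41, 41], direct)
  # a 12x9 rectangle evaluates 108 blocks (counted through a stub)
  rect <- cbind(c(30, 42, 42, 30), c(40, 40, 49, 49))
  counter <- 0L
  stub <- function(plane, partner, x0, y0, block_size) {
    counter <<- counter + 1L
    1
  }
  ms <- rolling_frc_map(pr$img1, list(rect), block_size = 64,
                        frc_fun = stub)
  expect_equal(counter, 12L * 9L)
  expect_equal(ms$n_evaluations, 108L)
})

test_that("blocks clamp inward at image borders", {
  pr <- make_pair(size = 96, seed = 52, gaussian_sd = 100)
  seen <- list()
  stub <- function(plane, partner, x0, y0, block_size) {
    seen[[length(seen) + 1L]] <<- c(x0, y0)
    1
  }
  corner <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))  # pixel (0,0)
  rolling_frc_map(pr$img1, list(corner), block_size = 64, frc_fun = stub)
  expect_equal(seen[[1]], c(0, 0))
  far <- cbind(c(95, 96, 96, 95), c(95, 95, 96, 96))  # pixel (95,95)
  rolling_frc_map(pr$img1, list(far), block_size = 64, frc_fun = stub)
  expect_equal(seen[[2]], c(96 - 64, 96 - 64))
  expect_error(rolling_frc_map(pr$img1, list(corner), block_size = 128),
               "block larger")
})

test_that("uniform-blur planes give flat rolling maps", {
  cv <- vapply(1:5, function(s) {
    pr <- make_pair(size = 128, seed = s, blur_sigma = 2,
                    gaussian_sd = 100)
    m <- rolling_frc_map(pr$img1, list(square_roi(128)))
    v <- m$values[!is.na(m$values)]
    stats::sd(v) / mean(v)
  }, numeric(1))
  expect_true(all(cv <= 0.2))
})

test_that("rolling and tiled means agree on uniform-blur planes", {
  pr <- make_pair(size = 128, seed = 53, blur_sigma = 2, gaussian_sd = 100)
  roi <- list(square_roi(128))
  tiled <- mtfrc_plane(pr$img1, roi)$summary$mtfrc_um
  rolled <- rolling_frc_map(pr$img1, roi)
  expect_lt(abs(mean(rolled$values, na.rm = TRUE) - tiled) / tiled, 0.15)
})

test_that("stride > 1 fills the ROI from the evaluation lattice", {
  pr <- make_pair(size = 96, seed = 54, blur_sigma = 1, gaussian_sd = 100)
  roi <- list(square_roi(96))
  m <- rolling_frc_map(pr$img1, roi, block_size = 64, stride = 8)
  expect_lt(m$n_evaluations, 96 * 96 / 32)
  expect_equal(sum(is.na(m$values)), 0)
})

test_that("median smoothing is an identity at radius 0 and on constants", {
  vals <- matrix(2.5, 32, 32)
  vals[1:4, 1:4] <- NA
  m <- structure(list(values = vals, block_size = 64, pixel_size = 0.1,
                      n_evaluations = 0L), class = "resolution_map")
  expect_identical(smooth_map(m, 0)$values, vals)
  sm <- smooth_map(m, 10)
  expect_identical(sm$values, vals)  # constant field unchanged, NAs kept
  expect_error(smooth_map(m, -1), "non-negative")
})

test_that("median smoothing removes isolated outliers and respects range", {
  vals <- matrix(1, 41, 41)
  vals[21, 21] <- 50
  m <- structure(list(values = vals, block_size = 64, pixel_size = 0.1,
                      n_evaluations = 0L), class = "resolution_map")
  sm <- smooth_map(m, 10)
  expect_equal(sm$values[21, 21], 1)
  expect_true(all(sm$values >= min(vals) & sm$values <= max(vals)))
  # undefined pixels stay undefined and do not pull on neighbours
  vals2 <- matrix(c(1, NA), 20, 20)
  m2 <- structure(list(values = vals2, block_size = 64, pixel_size = 0.1,
                       n_evaluations = 0L), class = "resolution_map")
  sm2 <- smooth_map(m2, 3)
  expect_identical(is.na(sm2$values), is.na(vals2))
  expect_true(all(sm2$values[!is.na(sm2$values)] == 1))
})

test_that("the disc median filter matches a direct clipped-window median", {
  set.seed(55)
  m <- matrix(sample(0:9, 25 * 30, TRUE) + 0, 25, 30)
  for (radius in c(1, 2.5)) {
    got <- mtfrc:::disc_median_filter(m, radius)
    for (k in 1:40) {
      i <- sample(25, 1); j <- sample(30, 1)
      vals <- c()
      for (di in -3:3) for (dj in -3:3) {
        if (di^2 + dj^2 <= radius^2 + 1e-9 &&
            i + di >= 1 && i + di <= 25 && j + dj >= 1 && j + dj <= 30)
          vals <- c(vals, m[i + di, j + dj])
      }
      expect_equal(got[i, j], stats::median(vals))
    }
  }
})

test_that("rendering clips to the physical scale with 'max+' semantics", {
  vals <- matrix(NA_real_, 2, 3)
  vals[1, 1] <- 7.5   # above scale max
  vals[1, 2] <- 7.0   # at scale max
  vals[1, 3] <- 0     # at scale min
  vals[2, 1] <- 3.5
  m <- structure(list(values = vals, block_size = 64, pixel_size = 0.1,
                      n_evaluations = 4L), class = "resolution_map")
  pal <- grDevices::hcl.colors(64, "viridis")
  arr <- render_map(m, scale = c(0, 7), palette = pal)
  expect_equal(dim(arr), c(2, 3, 3))
  expect_equal(arr[1, 1, ], arr[1, 2, ])          # 7.5 renders as 7.0
  expect_equal(arr[1, 3, ], as.numeric(grDevices::col2rgb(pal[1]) / 255))
  na_rgb <- as.numeric(grDevices::col2rgb("grey40") / 255)
  expect_equal(arr[2, 2, ], na_rgb)               # undefined -> background
  expect_error(render_map(m, scale = c(7, 0)), "min < max")
  # an all-above-scale map renders entirely at the top colour
  m$values[] <- 9
  arr2 <- render_map(m, scale = c(0, 7), palette = pal)
  top <- as.numeric(grDevices::col2rgb(pal[64]) / 255)
  expect_true(all(apply(arr2, c(1, 2), function(px) all(px == top))))
})

test_that("colourmap PNG export writes a decodable image", {
  vals <- matrix(runif(32 * 32, 0, 8), 32, 32)
  m <- structure(list(values = vals, block_size = 64, pixel_size = 0.1,
                      n_evaluations = 1024L), class = "resolution_map")
  path <- tempfile(fileext = ".png")
  write_colormap_png(m, path)
  expect_true(file.size(path) > 0)
  img <- png::readPNG(path)
  expect_gte(dim(img)[2], 32)  # map plus the colour bar panel
})
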