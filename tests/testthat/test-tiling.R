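test_that("tile enumeration reproduces the grid arithmetic", {
  # 1024x1024 full-image ROI, 64-px tiles: 16^2 = 256 tiles
  t1 <- enumerate_tiles(c(1024, 1024), list(square_roi(1024)), 64)
  expect_equal(nrow(t1), 256)
  # 128x128 full ROI, 64-px tiles: 4 tiles
  t2 <- enumerate_tiles(c(128, 128), list(square_roi(128)), 64)
  expect_equal(nrow(t2), 4)
  expect_equal(t2[, "x"], c(0, 64, 0, 64))
  expect_equal(t2[, "y"], c(0, 0, 64, 64))
  # a 10x10 ROI cannot contain any 64-px tile
  small <- cbind(c(20, 30, 30, 20), c(20, 20, 30, 30))
  expect_equal(nrow(enumerate_tiles(c(128, 128), list(small), 64)), 0)
})

test_that("tiles are disjoint, in-bounds, and grid-anchored", {
  poly <- cbind(c(10, 250, 250, 10), c(5, 5, 200, 200))
  tl <- enumerate_tiles(c(256, 256), list(poly), 32)
  expect_true(all(tl %% 32 == 0))
  expect_true(all(tl[, "x"] + 32 <= 256 & tl[, "y"] + 32 <= 256))
  expect_false(any(duplicated(paste(tl[, "x"], tl[, "y"]))))
  # full containment: every tile's pixels all inside the polygon mask
  mask <- polygon_mask(256, 256, list(poly))
  for (i in seq_len(nrow(tl)))
    expect_true(all(mask[tl[i, "y"] + 1:32, tl[i, "x"] + 1:32]))
})

test_that("containment fraction relaxes tile selection for thin features", {
  poly <- cbind(c(0, 128, 128, 0), c(0, 0, 40, 40))  # 40-px tall strip
  expect_equal(nrow(enumerate_tiles(c(128, 128), list(poly), 64)), 0)
  half <- enumerate_tiles(c(128, 128), list(poly), 64, containment = 0.5)
  expect_equal(nrow(half), 2)
  expect_error(enumerate_tiles(c(128, 128), list(poly), 64,
                               containment = 0), "containment")
})

test_that("tile size validation matches the contract", {
  roi <- list(square_roi(64))
  expect_error(enumerate_tiles(c(64, 64), roi, 6), "even integer")
  expect_error(enumerate_tiles(c(64, 64), roi, 63), "even integer")
  expect_error(enumerate_tiles(c(32, 32), roi, 64), "larger than image")
})

test_that("plane summary averages valid tiles only", {
  # 3 structured tiles + 1 constant (zero-information) tile in a 128x128
  # plane: mean over the valid three, fraction_valid 0.75
  set.seed(31)
  scene <- mtfrc:::make_scene(128, "filtered_noise", blur_sigma = 1)
  m <- mtfrc:::add_noise(scene, gaussian_sd = 100)
  m[65:128, 65:128] <- 7  # constant tile: no correlating frequencies
  pr <- mtfrc_plane(image_plane(m, 0.1), list(square_roi(128)))
  expect_equal(pr$summary$n_tiles, 4)
  expect_equal(pr$summary$n_valid, 3)
  expect_equal(pr$summary$fraction_valid, 0.75)
  ok <- pr$tiles$valid
  expect_equal(pr$summary$mtfrc_um, mean(pr$tiles$resolution_um[ok]))
  expect_equal(pr$tiles$status[!ok], "no_correlation")
})

test_that("a one-tile ROI reproduces that tile's FRC exactly", {
  set.seed(32)
  pr <- make_pair(size = 128, seed = 32, blur_sigma = 1.5,
                  gaussian_sd = 100)
  roi <- cbind(c(0, 64, 64, 0), c(0, 0, 64, 64))
  res <- mtfrc_plane(pr$img1, list(roi))
  expect_equal(res$summary$n_tiles, 1)
  direct <- single_image_frc(
    image_plane(pr$img1$pixels[1:64, 1:64], 0.1))$resolution
  expect_identical(res$summary$mtfrc_um, direct)
})

test_that("regions blurred more resolve worse", {
  worse <- vapply(1:20, function(s) {
    hp <- make_heterogeneous_plane(size = 256, sigmas = c(1, 3), seed = s)
    l <- mtfrc_plane(hp$plane, list(hp$roi_left))$summary$mtfrc_um
    r <- mtfrc_plane(hp$plane, list(hp$roi_right))$summary$mtfrc_um
    r > l
  }, logical(1))
  expect_gte(sum(worse), 19)
})

test_that("pair mode requires a matching partner", {
  pr <- make_pair(size = 64, seed = 33, gaussian_sd = 50)
  expect_error(mtfrc_plane(pr$img1, list(square_roi(64)), mode = "pair"),
               "partner")
  expect_error(mtfrc_plane(pr$img1, list(square_roi(64)), mode = "pair",
                           partner = image_plane(matrix(1, 32, 32), 0.1)),
               "mismatch")
  res <- mtfrc_plane(pr$img1, list(square_roi(64)), mode = "pair",
                     partner = pr$img2)
  expect_equal(res$summary$n_tiles, 1)
})

test_that("depth profile carries depths, counts and the validity flag", {
  st <- make_depth_stack(n_slices = 3, size = 128, seed = 41,
                         sigma_of_z = function(z) 1, z_step = 10)
  fit <- mtfrc(st, roi_all_slices(128, 3))
  p <- fit$profile
  expect_equal(nrow(p), 3)
  expect_equal(p$depth_um, c(0, 10, 20))
  expect_equal(p$n_tiles, rep(4, 3))
  expect_true(all(p$fraction_valid >= 0 & p$fraction_valid <= 1))
  expect_s3_class(fit, "mtfrc")
  expect_equal(as.data.frame(fit), p)
  expect_length(coef(fit), 3)
})

test_that("slices without an ROI entry contribute no rows", {
  st <- make_depth_stack(n_slices = 5, size = 128, seed = 42,
                         sigma_of_z = function(z) 1)
  roi <- roi_set(list("1" = square_roi(128), "3" = square_roi(128)))
  fit <- mtfrc(st, roi)
  expect_equal(fit$profile$z_index, c(1, 3))
  expect_error(mtfrc(st, roi_set(list("9" = square_roi(128)))),
               "outside the stack")
})

test_that("the validity rule keeps sub-threshold depths out of the plot only", {
  # build a 640x64 plane with 10 tiles, exactly one of which is constant:
  # fraction_valid = 0.9 < 0.95 => present in the profile, not reported
  set.seed(43)
  scene <- mtfrc:::make_scene(640, "filtered_noise", blur_sigma = 1)
  m <- mtfrc:::add_noise(scene, 100)[1:64, ]
  m[, 129:192] <- 0
  st <- z_stack(list(image_plane(m, 0.1)), z_step = 10)
  roi <- roi_set(list("0" = cbind(c(0, 640, 640, 0), c(0, 0, 64, 64))))
  fit <- mtfrc(st, roi)
  expect_equal(fit$profile$n_tiles, 10)
  expect_equal(fit$profile$fraction_valid, 0.9)
  expect_false(fit$profile$reported)
  # the profile row survives in the CSV ...
  csv <- tempfile(fileext = ".csv")
  write_profile_csv(fit, csv)
  expect_equal(nrow(utils::read.csv(csv)), 1)
  # ... but the plot draws nothing
  png_path <- tempfile(fileext = ".png")
  grDevices::png(png_path)
  drawn <- plot(fit)
  grDevices::dev.off()
  expect_equal(nrow(drawn), 0)
  # at a laxer threshold the same slice is reported
  fit2 <- mtfrc(st, roi, validity_threshold = 0.9)
  expect_true(fit2$profile$reported)
})

test_that("mtFRC degrades monotonically in a depth-degrading stack", {
  roi <- roi_all_slices(512, 10)
  for (seed in 1:3) {
    st <- make_depth_stack(n_slices = 10, size = 512, seed = seed,
                           sigma_of_z = function(z) 0.5 + 0.35 * z)
    p <- mtfrc(st, roi)$profile$mtfrc_um
    expect_lte(sum(diff(p) < -1e-9, na.rm = TRUE), 1)
  }
})
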