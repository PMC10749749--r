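test_that("sigma/FWHM conversion follows the Gaussian closed form", {
  expect_equal(sigma_to_fwhm(10), 23.5482, tolerance = 1e-5)
  expect_equal(fwhm_to_sigma(sigma_to_fwhm(3.2)), 3.2, tolerance = 1e-12)
})

test_that("bead extraction finds, separates and deduplicates candidates", {
  bb <- make_bead_stack(n_beads = 5, size = 200, n_slices = 9,
                        min_separation = 48, seed = 71)
  subs <- extract_bead_substacks(bb$stack, box_size = 48,
                                 min_separation = 48)
  expect_length(subs, 5)
  # two spots 3 px apart with a wide separation radius: brighter kept
  m <- matrix(0, 128, 128)
  m[60, 60] <- 800; m[60, 63] <- 1000
  st <- z_stack(list(image_plane(m, 0.1)), 1)
  subs2 <- extract_bead_substacks(st, box_size = 64, min_separation = 64)
  expect_length(subs2, 1)
  expect_equal(subs2[[1]]$seed_peak, 1000)
  # blank stack yields an empty list
  blank <- z_stack(list(image_plane(matrix(0, 64, 64), 0.1)), 1)
  expect_length(extract_bead_substacks(blank), 0)
})

test_that("centre finding is median-filtered, exact, and tie-stable", {
  # noiseless Gaussian spot at (31, 31, 5) in a 64x64x11 substack
  bb <- make_bead_stack(n_beads = 1, size = 64, n_slices = 11,
                        min_separation = 32, poisson = FALSE, seed = 72)
  sp <- exp(-(outer((0:63 - 31)^2, (0:63 - 31)^2, "+")) / (2 * 4))
  planes <- lapply(0:10, function(z)
    image_plane(1000 * exp(-(z - 5)^2 / 2) * sp + 1, 0.1, z))
  st <- z_stack(planes, 0.5)
  expect_equal(locate_centre(st), c(x = 31L, y = 31L, z = 5L))
  # a single hot pixel elsewhere is suppressed by the radius-1 median
  planes[[3]]$pixels[10, 50] <- 1e6
  st2 <- z_stack(planes, 0.5)
  expect_equal(locate_centre(st2), c(x = 31L, y = 31L, z = 5L))
  # ties resolve to the smallest (z, y, x)
  flat <- z_stack(list(image_plane(matrix(5, 16, 16), 0.1),
                       image_plane(matrix(5, 16, 16), 0.1)), 1)
  expect_equal(locate_centre(flat), c(x = 0L, y = 0L, z = 0L))
})

test_that("an exact Gaussian profile recovers sigma to machine precision", {
  # sigma = 10 px, pixel 0.1 um -> FWHM = 2 sqrt(2 ln 2) um = 2.35482 um
  u <- 0:63
  spot <- outer(500 * exp(-(u - 31)^2 / (2 * 100)),
                500 * exp(-(u - 31)^2 / (2 * 100))) / 500 + 50
  st <- z_stack(list(image_plane(spot, 0.1)), 1)
  fw <- fit_fwhm(st, c(31, 31, 0))
  expect_true(fw$ok)
  expect_equal(fw$fwhm, sigma_to_fwhm(10) * 0.1, tolerance = 1e-6)
  expect_equal(fw$fwhm_x, fw$fwhm_y, tolerance = 1e-9)
  # the averaging identity FWHM = (FWHM_x + FWHM_y) / 2
  expect_equal(fw$fwhm, (fw$fwhm_x + fw$fwhm_y) / 2, tolerance = 1e-12)
})

test_that("FWHM fitting is invariant to intensity scale and offset", {
  u <- 0:63
  spot <- outer(exp(-(u - 30)^2 / (2 * 9)), exp(-(u - 33)^2 / (2 * 16)))
  f1 <- fit_fwhm(z_stack(list(image_plane(1000 * spot + 10, 0.1)), 1),
                 c(33, 30, 0))
  f2 <- fit_fwhm(z_stack(list(image_plane(5500 * spot + 300, 0.1)), 1),
                 c(33, 30, 0))
  expect_equal(f1$fwhm_x, f2$fwhm_x, tolerance = 1e-7)
  expect_equal(f1$fwhm_y, f2$fwhm_y, tolerance = 1e-7)
})

test_that("degenerate profiles are flagged rather than fitted", {
  flat <- z_stack(list(image_plane(matrix(7, 32, 32), 0.1)), 1)
  fw <- fit_fwhm(flat, c(16, 16, 0))
  expect_false(fw$ok)
  expect_true(is.na(fw$fwhm))
  expect_error(fit_fwhm(z_stack(list(image_plane(matrix(1, 5, 5), 0.1)),
                                1), c(2, 2, 0)), "at least 7 samples")
})

test_that("bead FRC uses a centred, inward-clamped single-image tile", {
  bb <- make_bead_stack(n_beads = 1, size = 96, n_slices = 7,
                        min_separation = 48, seed = 73)
  subs <- extract_bead_substacks(bb$stack, box_size = 96,
                                 min_separation = 48)
  ctr <- locate_centre(subs[[1]]$stack)
  r <- bead_frc(subs[[1]]$stack, ctr, tile = 64)
  # 64-px tile means 32x32 sub-images
  expect_equal(r$curve$image_side, 32)
  expect_equal(r$curve$pixel_size, 2 * 0.0931)
  # corner centre still gets a full tile
  r2 <- bead_frc(subs[[1]]$stack, c(1, 1, ctr[[3]]), tile = 64)
  expect_equal(r2$curve$image_side, 32)
})

test_that("simulated beads recover the convolved FWHM and a flat trend", {
  bb <- make_bead_stack(n_beads = 30, size = 448, n_slices = 31, seed = 74)
  tab <- analyze_beads(bb$stack)
  expect_equal(nrow(tab), 30)
  truth <- bb$truth$fwhm_um[1]
  expect_lt(abs(mean(tab$fwhm_um, na.rm = TRUE) - truth) / truth, 0.05)
  # per-record Gaussian identity: fwhm_k = 2 sqrt(2 ln 2) sigma_k
  ok <- tab$flags == ""
  expect_equal(tab$fwhm_x_um[ok], sigma_to_fwhm(tab$sigma_x_um[ok]),
               tolerance = 1e-9)
  expect_equal(tab$fwhm_um[ok], (tab$fwhm_x_um[ok] + tab$fwhm_y_um[ok]) / 2,
               tolerance = 1e-9)
  expect_true(all(tab$peak_norm > 0 & tab$peak_norm <= 1))
  # constant ground truth: FWHM-vs-depth slope within 2 SE of zero
  s <- bead_summary(tab)
  f <- s$fits$fwhm_vs_depth
  expect_lt(abs(f$slope), 2 * f$slope_se + 1e-12)
})

test_that("normalized peak decay recovers the simulated decay length", {
  bb <- make_bead_stack(n_beads = 60, size = 640, n_slices = 101,
                        intensity_decay_length = 25,
                        amplitude_jitter = 0.1, seed = 75)
  tab <- analyze_beads(bb$stack)
  s <- bead_summary(tab)
  expect_false(is.null(s$decay))
  expect_lt(abs(s$decay$length_um - 25) / 25, 0.10)
})

test_that("summary statistics follow their definitions on tiny tables", {
  rec <- data.frame(depth_um = c(0, 10), fwhm_um = c(0.4, 0.5),
                    frc_um = c(0.4, 0.5), peak_norm = c(1, 0.5))
  s <- bead_summary(rec)
  # FRC == FWHM record-wise: zero mean and SD of percentage differences
  expect_equal(s$frc_vs_fwhm_pct$mean, 0)
  expect_equal(s$frc_vs_fwhm_pct$sd, 0)
  # two points: perfect correlation
  expect_equal(abs(s$fits$frc_vs_fwhm$r), 1)
  expect_equal(s$fits$fwhm_vs_depth$slope, 0.01, tolerance = 1e-12)
  expect_error(bead_summary(rec[1, ]), "at least 2")
  # per-bead CSV export
  path <- tempfile(fileext = ".csv")
  write_bead_csv(structure(rec, class = c("bead_table", "data.frame")),
                 path)
  expect_equal(nrow(utils::read.csv(path)), 2)
})
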