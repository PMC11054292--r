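test_that("z grid uses the half-open segment-start convention", {
  g <- make_z_grid(-10, 10, 0.05)
  expect_length(g, 400)
  expect_equal(g[1], -10)
  expect_equal(g[400], 9.95)
  expect_equal(diff(g), rep(0.05, 399), tolerance = 1e-12)

  expect_equal(make_z_grid(0, 1, 0.5), c(0, 0.5))

  # independent enumeration by repeated addition
  oracle <- local({
    v <- -1; out <- v
    while (v + 0.05 < 1 - 1e-9) { v <- v + 0.05; out <- c(out, v) }
    out
  })
  g2 <- make_z_grid(-1, 1, 0.05)
  expect_length(g2, 40)
  expect_equal(g2, oracle, tolerance = 1e-9)
  expect_equal(g2[1], -1)
  expect_equal(g2[40], 0.95)
})

test_that("non-divisible z range is rejected with the remainder named", {
  expect_error(make_z_grid(0, 1, 0.3), "remainder")
  expect_error(optical_config(z_step = -0.05), "positive")
  expect_error(optical_config(z_min = 5, z_max = -5), "smaller")
})

test_that("noise-free pattern is radially symmetric and compact at focus", {
  cfg <- mini_optical()
  p0 <- simulate_bead_pattern(mini_classes$small, 0, cfg)
  px <- p0$pixels - mini_classes$small$pattern$background
  n <- nrow(px)
  x <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  centroid <- c(sum(px * x), sum(px * t(x))) / sum(px)
  expect_lt(max(abs(centroid - (n - 1) / 2)), 1e-6)

  # smallest second moment at z = 0, non-decreasing in |z|
  for (cl in mini_classes) {
    zs <- seq(0, 10, by = 0.5)
    mom <- vapply(zs, function(z) {
      p <- simulate_bead_pattern(cl, z, optical_config())
      radial_second_moment(p$pixels, background = cl$pattern$background)
    }, 0)
    expect_true(all(diff(mom) >= -1e-9))
    momn <- vapply(zs, function(z) {
      p <- simulate_bead_pattern(cl, -z, optical_config())
      radial_second_moment(p$pixels, background = cl$pattern$background)
    }, 0)
    expect_true(all(diff(momn) >= -1e-9))
  }
})

test_that("above- and below-focus patterns are distinguishable", {
  cfg <- optical_config()
  pp <- simulate_bead_pattern(mini_classes$small, 5, cfg)
  pm <- simulate_bead_pattern(mini_classes$small, -5, cfg)
  expect_lt(patch_ncc(pp$pixels, pm$pixels), 0.99)

  # sign identifiability: the mirror pattern is less similar than the
  # next grid neighbour, for every |z| >= 1
  for (cl in mini_classes) {
    for (z in seq(1, 9.5, by = 0.5)) {
      a <- simulate_bead_pattern(cl, z, cfg)$pixels
      b <- simulate_bead_pattern(cl, -z, cfg)$pixels
      nb <- simulate_bead_pattern(cl, z + cfg$z_step, cfg)$pixels
      expect_lt(patch_ncc(a, b), patch_ncc(a, nb))
    }
  }
})

test_that("bigger defocus spreads the pattern", {
  cfg <- optical_config()
  m8 <- radial_second_moment(
    simulate_bead_pattern(mini_classes$big, 8, cfg)$pixels,
    background = mini_classes$big$pattern$background)
  m2 <- radial_second_moment(
    simulate_bead_pattern(mini_classes$big, 2, cfg)$pixels,
    background = mini_classes$big$pattern$background)
  expect_gte(m8, m2)
})

test_that("out-of-range z is rejected", {
  expect_error(simulate_bead_pattern(mini_classes$small, 3, mini_optical()),
               "outside")
})

test_that("radial symmetry center recovers known spot positions", {
  s <- gaussian_spot(41, 20, 20)
  expect_lt(max(abs(radial_symmetry_center(s) - c(20, 20))), 1e-3)

  s2 <- gaussian_spot(41, 17.30, 21.80)
  expect_lt(max(abs(radial_symmetry_center(s2) - c(17.30, 21.80))), 0.05)

  # defocused ring pattern at a sub-pixel center
  cfg <- mini_optical()
  p <- simulate_bead_pattern(mini_classes$small, 1.5, cfg,
                             center = c(30.27, 33.61))
  expect_lt(max(abs(radial_symmetry_center(p$pixels) - c(30.27, 33.61))), 0.05)
})

test_that("localization stays sub-pixel under noise (Monte Carlo)", {
  cfg <- optical_config(seed = 3)
  errs <- vapply(seq_len(200), function(i) {
    ctr <- 31.5 + with_seed(substream_seed(3, paste0("mc-ctr/", i)),
                            runif(2, -0.5, 0.5))
    p <- with_seed(substream_seed(3, paste0("mc-noise/", i)),
                   simulate_bead_pattern(mini_classes$small, 3, cfg,
                                         center = ctr, noise_sd = 0.02))
    sqrt(sum((radial_symmetry_center(p$pixels) - ctr)^2))
  }, 0)
  expect_lt(mean(errs), 0.5)
})

test_that("degenerate images are rejected", {
  expect_error(radial_symmetry_center(matrix(0.5, 11, 11)), "degenerate")
  expect_error(radial_symmetry_center(matrix(0.5, 3, 3)))
})

test_that("library size is classes x grid positions", {
  lib <- mini_library()
  expect_equal(library_size(lib), 2 * 8)
  expect_equal(length(lib$z_grid), 8)

  cfg1 <- optical_config(z_min = 0, z_max = 1, z_step = 0.5)
  one <- build_calibration_library(mini_classes["small"], cfg1)
  expect_equal(library_size(one), 2)

  cfg3 <- optical_config(z_min = -1, z_max = 1, z_step = 0.1)
  cls3 <- c(mini_classes,
            list(tiny = bead_class("tinybead", 0.5, 48)))
  three <- build_calibration_library(cls3, cfg3)
  expect_equal(library_size(three), 3 * 20)

  expect_error(build_calibration_library(list(), mini_optical()), "non-empty")
})

test_that("identical seeds give bit-identical libraries", {
  a <- build_calibration_library(mini_classes, mini_optical(seed = 5))
  b <- build_calibration_library(mini_classes, mini_optical(seed = 5))
  expect_identical(a, b)
})

test_that("calibrated patch centers track the true sub-pixel jitter", {
  lib <- mini_library()
  for (lab in names(lib$patches)) {
    nominal <- (mini_classes[[lab]]$patch_size_px - 1) / 2
    for (k in seq_along(lib$z_grid)) {
      s <- substream_seed(lib$config$seed, sprintf("calib/%s/%d", lab, k))
      true_ctr <- nominal + with_seed(s, runif(2, -0.5, 0.5))
      expect_lt(max(abs(lib$patches[[lab]][[k]]$center - true_ctr)), 0.02)
    }
  }
})

test_that("library round-trips through TIFF + CSV", {
  lib <- mini_library()
  dir <- withr::local_tempdir()
  write_calibration_library(lib, dir)
  idx <- read.csv(file.path(dir, "index.csv"))
  expect_equal(nrow(idx), library_size(lib))
  back <- read_calibration_library(dir)
  expect_equal(back$z_grid, lib$z_grid)
  expect_equal(back$patches$small[[3]]$center, lib$patches$small[[3]]$center)
  # pixels survive 16-bit quantization
  expect_lt(max(abs(back$patches$big[[5]]$pixels -
                    lib$patches$big[[5]]$pixels)), 1 / 65535)
})
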