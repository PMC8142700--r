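test_that("voronoi_background is deterministic and respects its modes", {
  b1 <- voronoi_background(32, 10, seed = 5)
  b2 <- voronoi_background(32, 10, seed = 5)
  expect_identical(unclass(b1)[], unclass(b2)[])

  g <- voronoi_background(32, 10, achromatic = TRUE, seed = 6)
  p <- pixel_matrix(g)
  expect_equal(max(abs(p[, 1] - p[, 2])), 0)
  expect_equal(max(abs(p[, 2] - p[, 3])), 0)

  expect_error(voronoi_background(32, 1, seed = 1), "at least 2")
})

test_that("two-site tessellation splits along the perpendicular bisector", {
  b <- voronoi_background(24, 2, seed = 9)
  sites <- attr(b, "sites")
  cells <- attr(b, "cells")
  expect_equal(length(unique(as.vector(cells))), 2L)
  # brute-force nearest-site check at every pixel
  for (px in seq_len(24 * 24)) {
    i <- (px - 1) %% 24 + 1; j <- (px - 1) %/% 24 + 1
    d <- (j - sites[, 1])^2 + (i - sites[, 2])^2
    expect_identical(cells[i, j], which.min(d))
  }
})

test_that("mix_transmission follows the stated mixing equation", {
  bases <- transmission_bases()
  m <- mix_transmission(1, 1, 1, bases)
  expect_equal(m$values, 0.5 * (bases$red$values + bases$blue$values),
               tolerance = 1e-12)
  expect_equal(attr(m, "clip_fraction"), 0)

  # linear in ld_scale
  m1 <- mix_transmission(0.5, 0.25, 1, bases)
  m2 <- mix_transmission(0.5, 0.25, 0.68, bases)
  expect_equal(m2$values, 0.68 * m1$values, tolerance = 1e-12)

  # the 4 x 4 x 2 design yields 32 distributions; convex mixtures
  # (weights in [0, 1]) never clip, and the extrapolated corners of the
  # [-1, 1] design are clipped with a report rather than silently
  alphas <- seq(-1, 1, length.out = 4)
  grid32 <- expand.grid(rg = alphas, by = alphas, ld = c(0.68, 1))
  expect_equal(nrow(grid32), 32L)
  clip <- apply(grid32, 1, function(r) {
    attr(mix_transmission(r[1], r[2], r[3], bases), "clip_fraction")
  })
  convex <- grid32$rg >= 0 & grid32$rg <= 1 & grid32$by >= 0 & grid32$by <= 1
  expect_true(all(clip[convex] == 0))
  expect_true(all(clip >= 0 & clip <= 1))
  expect_true(any(clip > 0))   # the corners really are extrapolations

  bad <- spectrum(seq(400, 700, length.out = 31), rep(0.5, 31))
  expect_error(mix_transmission(1, 1, 1,
                                list(red = bad, green = bases$green,
                                     blue = bases$blue, yellow = bases$yellow)),
               "common wavelength grid")
})

test_that("filter_transmission combines the normalized bases", {
  bases <- flat_filter_bases()
  f <- filter_transmission(filter_params(0.5, 0.5, 0.5), bases)
  expect_equal(f$values, 0.25 * (bases$red$values + bases$green$values +
                                   bases$blue$values + bases$yellow$values),
               tolerance = 1e-12)
  f2 <- filter_transmission(filter_params(0.4, 1, 1), bases)
  expect_equal(f2$values, pmin(0.4 * (bases$red$values + bases$blue$values), 1),
               tolerance = 1e-12)
  f3 <- filter_transmission(filter_params(0, 0.3, 0.7), bases)
  expect_true(all(f3$values == 0))
  expect_true(all(vapply(bases, function(b) max(b$values), 0) == 1))
})

test_that("mix_illuminants prescales then convex-combines", {
  a <- flat_spectrum(1); b <- flat_spectrum(1)
  m <- mix_illuminants(a, b, w = 0.7, prescale = 0.5)
  expect_true(all(abs(m$values - 0.5) < 1e-12))

  m2 <- mix_illuminants(a, b, w = 1, prescale = 0.5)
  expect_equal(m2$values, 0.5 * a$values)

  set.seed(11)
  s1 <- spectrum(test_grid, runif(47)); s2 <- spectrum(test_grid, runif(47))
  m3 <- mix_illuminants(s1, s2, w = 0.7, prescale = 0.5)
  for (k in c(1, 10, 20, 35, 47)) {
    expect_equal(m3$values[k], 0.5 * (0.7 * s1$values[k] + 0.3 * s2$values[k]),
                 tolerance = 1e-12)
  }
})

test_that("simulate_affine_scene closes the loop with the fitters", {
  bg <- voronoi_background(40, 20, seed = 12)
  obj <- matrix(FALSE, 40, 40); obj[5:35, 5:35] <- TRUE
  M0 <- matrix(c(0.5, 0.05, 0, 0.02, 0.6, 0.01, 0, 0.03, 0.45), 3, 3)
  t0 <- c(0.1, 0.02, 0.05)
  sc <- simulate_affine_scene(bg, obj, M = M0, t = t0)
  pr <- build_pairs(sc$unfiltered, sc$filtered, obj, space = "linearRGB",
                    cal = test_cal)
  fit <- fit_affine12(pr)
  expect_lt(max(abs(fit$M - M0)), 1e-8)
  expect_lt(max(abs(fit$t - t0)), 1e-8)

  # identity transform leaves the pixel data bit-exact
  sc2 <- simulate_affine_scene(bg, obj, M = diag(3), t = c(0, 0, 0))
  expect_identical(as.vector(sc2$filtered), as.vector(sc2$unfiltered))

  # seeded noise is reproducible
  sc3 <- simulate_affine_scene(bg, obj, beta = 0.5, t = t0,
                               noise_sigma = 0.01, seed = 99)
  sc4 <- simulate_affine_scene(bg, obj, beta = 0.5, t = t0,
                               noise_sigma = 0.01, seed = 99)
  expect_identical(unclass(sc3$filtered)[], unclass(sc4$filtered)[])
})

effects_off <- function(...) {
  scene_spec(size = 48L, n_sites = 15L,
             specular_fraction = 0, caustic_gain = 0, shadow_gain = 1,
             refraction_magnitude = 0, body_variation = 0, ...)
}

test_that("perfectly clear glass leaves the scene untouched", {
  sp <- effects_off(seed = 13, transmission = flat_spectrum(1), passes = 1L)
  sc <- simulate_glass_scene(sp, test_cal)
  expect_lt(max(abs(sc$filtered - sc$unfiltered)), 1e-12)
})

test_that("flat transmission factors out as tau^passes", {
  tau0 <- 0.8
  sp <- effects_off(seed = 14, background = "uniform",
                    transmission = flat_spectrum(tau0), passes = 2L)
  sc <- simulate_glass_scene(sp, test_cal)
  lms_f <- convert_space(sc$filtered, "LMS", test_cal)
  lms_u <- convert_space(sc$unfiltered, "LMS", test_cal)
  obj <- sc$masks$object
  ratio <- pixel_matrix(lms_f, obj) / pixel_matrix(lms_u, obj)
  expect_lt(max(abs(ratio - tau0^2)), 1e-10)

  # with a uniform background the region-ratio statistic equals tau^2 too
  bg <- background_mask(obj)
  expect_triplet_equal(rmc(lms_f, obj, bg), rep(tau0^2, 3), 1e-10)
})

test_that("spectrally flat backgrounds make the filter an exact diagonal map", {
  sp <- effects_off(seed = 15, background = "achromatic_voronoi")
  sc <- simulate_glass_scene(sp, test_cal)
  obj <- sc$masks$object
  lms_f <- pixel_matrix(convert_space(sc$filtered, "LMS", test_cal), obj)
  lms_u <- pixel_matrix(convert_space(sc$unfiltered, "LMS", test_cal), obj)
  # per-channel ratio is the same at every pixel: a diagonal linear map
  ratio <- lms_f / lms_u
  expect_lt(max(apply(ratio, 2, function(x) diff(range(x)))), 1e-10)
  expect_true(all(ratio > 0 & ratio < 1))

  # the affine fit reaches the RRPE ceiling (the gray-line data are
  # rank-deficient for a full matrix, which the fitter reports)
  pr <- build_pairs(sc$unfiltered, sc$filtered, obj, space = "LMS",
                    cal = test_cal)
  expect_warning(fit <- fit_affine12(pr), "rank-deficient")
  expect_gte(fit$rrpe, 0.999)
})

test_that("glass scenes are deterministic and keep their mask bookkeeping", {
  sc1 <- glass_scene(16)
  sc2 <- glass_scene(16)
  expect_identical(unclass(sc1$filtered)[], unclass(sc2$filtered)[])
  expect_identical(unclass(sc1$unfiltered)[], unclass(sc2$unfiltered)[])

  m <- sc1$masks
  expect_true(all(m$object[m$highlight]))          # highlight inside object
  expect_false(any(m$caustic & m$object))
  expect_false(any(m$shadow & m$object))
  expect_gt(sum(m$highlight), 0)
  expect_lte(sum(m$highlight), 0.05 * sum(m$object) + 5)
})

test_that("filters only absorb: luminance never increases with effects off", {
  sp <- effects_off(seed = 17)
  sc <- simulate_glass_scene(sp, test_cal)
  lu <- luminance_map(sc$unfiltered, test_cal)
  lf <- luminance_map(sc$filtered, test_cal)
  expect_true(all(lf <= lu + 1e-12))
})

test_that("render_flat_filter processes only the disk", {
  bg <- voronoi_background(40, 12, achromatic = TRUE, seed = 18)
  ill <- default_illuminant("white")

  el1 <- render_flat_filter(bg, flat_spectrum(1), ill, cal = test_cal)
  el0 <- render_flat_filter(bg, flat_spectrum(0), ill, cal = test_cal)
  disk <- attr(el1, "disk_mask")

  # transmission 1: the whole image, disk included, equals the direct view
  # g * illuminant, assembled here from the colorimetry primitives
  g <- pixel_matrix(bg)[, 1]
  lms_I <- spectrum_to_tristimulus(ill, test_fund)
  m <- calibration_to_lms_matrix(test_cal, test_fund)
  direct <- outer(g, as.numeric(solve(m) %*% lms_I))
  expect_equal(pixel_matrix(el1), direct, tolerance = 1e-12)

  # transmission 0: disk black
  expect_true(all(pixel_matrix(el0, disk) == 0))
  expect_gt(min(pixel_matrix(el0, !disk)[, 1]), 0)

  # flat tau, 2 passes: disk luminance scaled by tau^2
  tau0 <- 0.6
  el <- render_flat_filter(bg, flat_spectrum(tau0), ill, passes = 2L, cal = test_cal)
  lum_el <- luminance_map(el, test_cal)
  lum_bg <- luminance_map(el1, test_cal)
  expect_equal(lum_el[disk], tau0^2 * lum_bg[disk], tolerance = 1e-10)
  expect_equal(lum_el[!disk], lum_bg[!disk], tolerance = 1e-12)

  expect_error(render_flat_filter(bg, flat_spectrum(1), ill,
                                  region = list(cx = 2, cy = 2, r = 10),
                                  cal = test_cal), "outside the image")
  chrom <- voronoi_background(40, 12, seed = 19)
  expect_error(render_flat_filter(chrom, flat_spectrum(1), ill, cal = test_cal),
               "achromatic")
})

test_that("scene_spec validates its invariants", {
  expect_error(scene_spec(size = 8, seed = 1))
  expect_error(scene_spec(seed = 1, specular_fraction = 0.2))
  expect_error(scene_spec(size = 32))   # missing seed
  expect_error(scene_spec(seed = 1, transmission = flat_spectrum(1.5)))
})
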