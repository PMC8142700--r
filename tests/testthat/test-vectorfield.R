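lattice2d <- function(center, half, n = 25L) {
  as.matrix(expand.grid(seq(center[1] - half, center[1] + half, length.out = n),
                        seq(center[2] - half, center[2] + half, length.out = n)))
}

affine_field_samples <- function(seed, n_lat = 25L) {
  set.seed(seed)
  M <- matrix(runif(4, -0.3, 0.3), 2, 2)
  diag(M) <- runif(2, 0.2, 0.6)
  t0 <- runif(2, -0.5, 0.5)
  p_star <- as.numeric(solve(diag(2) - M, t0))
  tails <- lattice2d(p_star, 2, n_lat)
  tips <- tails %*% t(M) + matrix(t0, nrow(tails), 2, byrow = TRUE)
  list(samples = field_samples(tails, tips), M = M, t = t0, p_star = p_star)
}

test_that("build_field pairs colours per pixel, preserving one-to-many tails", {
  img <- random_rgb_image(41, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  f0 <- build_field(img, img, mask, space = "LMS", cal = test_cal)
  expect_equal(f0$tails, f0$tips)

  # uniform wall, varying filter: identical tails, differing tips
  wall <- color_image(array(0.5, c(4, 4, 3)), "linearRGB")
  filt <- random_rgb_image(42, 4, 4)
  f1 <- build_field(wall, filt, matrix(TRUE, 4, 4), space = "LMS", cal = test_cal)
  expect_equal(max(apply(f1$tails, 2, function(x) diff(range(x)))), 0)
  expect_gt(max(apply(f1$tips, 2, function(x) diff(range(x)))), 0)

  # 5-pixel toy equals per-pixel lookup
  mask5 <- matrix(FALSE, 6, 6); mask5[c(1, 7, 13, 22, 35)] <- TRUE
  a <- random_rgb_image(43, 6, 6); b <- random_rgb_image(44, 6, 6)
  f2 <- build_field(a, b, mask5, space = "LMS", cal = test_cal)
  la <- pixel_matrix(convert_space(a, "LMS", test_cal))
  lb <- pixel_matrix(convert_space(b, "LMS", test_cal))
  expect_equal(f2$tails, la[c(1, 7, 13, 22, 35), ])
  expect_equal(f2$tips, lb[c(1, 7, 13, 22, 35), ])
})

test_that("interpolate_field averages within centred boxes", {
  # single sample: its own vector at the containing grid point, zeros elsewhere
  s1 <- field_samples(matrix(c(0.31, 0.52), 1), matrix(c(0.9, 1.1), 1))
  g1 <- interpolate_field(s1, 5)
  occ <- which(g1$counts > 0)
  expect_length(occ, 1L)
  expect_equal(g1$vectors[occ, ], c(0.9 - 0.31, 1.1 - 0.52))
  expect_true(all(g1$vectors[-occ, ] == 0))

  # two samples in one box: component-wise mean
  tails <- rbind(c(0.50, 0.50), c(0.501, 0.501))
  tips <- rbind(c(0.7, 0.4), c(0.3, 0.9))
  g2 <- interpolate_field(field_samples(tails, tips), 4)
  occ2 <- which(g2$counts == 2)
  expect_length(occ2, 1L)
  expect_equal(g2$vectors[occ2, ], colMeans(tips - tails))

  # random cloud vs brute-force box averaging
  set.seed(45)
  tails3 <- matrix(runif(40), 20, 2)
  tips3 <- matrix(runif(40), 20, 2)
  n <- 7L
  g3 <- interpolate_field(field_samples(tails3, tips3), n)
  centers1 <- seq(g3$box_min[1], g3$box_max[1], length.out = n)
  centers2 <- seq(g3$box_min[2], g3$box_max[2], length.out = n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    inbox <- abs(tails3[, 1] - centers1[i]) <= g3$step[1] / 2 &
             abs(tails3[, 2] - centers2[j]) <= g3$step[2] / 2
    cell <- i + (j - 1) * n
    if (any(inbox)) {
      expect_equal(g3$vectors[cell, ],
                   colMeans((tips3 - tails3)[inbox, , drop = FALSE]),
                   tolerance = 1e-12)
    } else {
      expect_equal(g3$vectors[cell, ], c(0, 0))
    }
  }
})

test_that("interpolation conserves occupied-cell sums at every resolution", {
  set.seed(46)
  s <- field_samples(matrix(runif(60), 30, 2), matrix(runif(60), 30, 2))
  total <- colSums(s$tips - s$tails)
  for (n in c(5L, 10L, 20L, 40L)) {
    g <- interpolate_field(s, n)
    expect_lt(max(abs(colSums(g$vectors * g$counts) - total)), 1e-12)
    expect_equal(sum(g$counts), 30L)   # binning never loses samples
  }
})

test_that("degenerate bounding-box axes are padded with a warning", {
  s <- field_samples(rbind(c(0, 0.5), c(1, 0.5)), rbind(c(0.2, 0.5), c(0.8, 0.5)))
  expect_warning(g <- interpolate_field(s, 5), "degenerate")
  expect_true(all(g$box_max > g$box_min))
})

test_that("binning key is switchable between tail, tip and midpoint", {
  s <- field_samples(matrix(c(0.1, 0.1), 1), matrix(c(0.9, 0.9), 1))
  gt <- interpolate_field(s, 5, bin_on = "tail")
  gp <- interpolate_field(s, 5, bin_on = "tip")
  expect_equal(which(gt$counts > 0), 1L)          # tail sits at box_min corner
  expect_equal(which(gp$counts > 0), 25L)         # tip at box_max corner
})

test_that("streamlines follow the field to its sink", {
  # uniform field: straight line along the direction
  tails <- lattice2d(c(0, 0), 1, 10)
  tips <- sweep(tails, 2, c(0.2, 0.1), "+")
  g <- interpolate_field(field_samples(tails, tips), 10)
  sl <- trace_streamlines(g, seeds = matrix(c(-0.8, -0.8), 1), max_steps = 500)
  pts <- sl[[1]]$points
  # the line runs until it reaches the box edge or the empty frontier where
  # the interpolated field fades to zero
  expect_true(sl[[1]]$termination %in% c("left_box", "stagnation"))
  expect_gt(nrow(pts), 10)
  d <- sweep(pts, 2, pts[1, ])
  cross <- d[, 1] * 0.1 - d[, 2] * 0.2     # collinearity with (0.2, 0.1)
  expect_lt(max(abs(cross)), 1e-9)

  # radial sink v(p) = c - p: every seed ends within one grid step of c
  cc <- c(0.3, -0.2)
  tails2 <- lattice2d(cc, 1.5, 20)
  tips2 <- matrix(cc, nrow(tails2), 2, byrow = TRUE)
  g2 <- interpolate_field(field_samples(tails2, tips2), 20)
  sl2 <- trace_streamlines(g2)
  for (s in sl2) {
    expect_lt(sqrt(sum((s$points[nrow(s$points), ] - cc)^2)), max(g2$step))
  }

  # seed outside the box
  sl3 <- trace_streamlines(g2, seeds = matrix(c(99, 99), 1))
  expect_identical(sl3[[1]]$termination, "left_box")
  expect_equal(nrow(sl3[[1]]$points), 1L)
})

test_that("contracting affine fields converge to the analytic fixed point", {
  af <- affine_field_samples(47)
  g <- interpolate_field(af$samples, 20)
  sl <- trace_streamlines(g)
  ends <- t(vapply(sl, function(s) s$points[nrow(s$points), ], numeric(2)))
  dist <- sqrt(rowSums(sweep(ends, 2, af$p_star)^2))
  expect_lt(max(dist), max(g$step))
})

test_that("affine_fixed_point solves the stationarity equation", {
  pairs <- color_pairs(matrix(runif(60), 20, 3),
                       matrix(runif(60), 20, 3))
  f4 <- fit_affine4(pairs)
  f4$beta <- 0.5; f4$t <- c(0.2, 0.2, 0.2)
  expect_equal(affine_fixed_point(f4)$point, c(0.4, 0.4, 0.4))

  f12 <- fit_affine12(pairs)
  f12$M <- matrix(0, 3, 3); f12$t <- c(1, 2, 3)
  expect_equal(affine_fixed_point(f12)$point, c(1, 2, 3))

  # non-contracting maps are flagged, not solved
  f12$M <- diag(3) * 1.2
  expect_true(affine_fixed_point(f12)$diverged)
  f4$beta <- 1
  expect_true(affine_fixed_point(f4)$diverged)

  # power-iteration oracle on random contracting maps
  set.seed(48)
  for (i in 1:5) {
    M <- matrix(runif(9, -0.2, 0.2), 3, 3); diag(M) <- runif(3, 0.1, 0.5)
    t0 <- runif(3, -1, 1)
    f12$M <- M; f12$t <- t0; f12$dims <- 3L
    p <- affine_fixed_point(f12)$point
    for (j in 1:10) {
      x <- runif(3, -2, 2)
      for (k in 1:300) x <- as.numeric(M %*% x + t0)
      expect_lt(sqrt(sum((x - p)^2)), 1e-6)
    }
  }
})

test_that("field_convergence_point finds the crossing of the vectors", {
  # perfect radial sink: exact recovery, zero residual
  cc <- c(1, -2)
  tails <- lattice2d(cc, 3, 9)
  tails <- tails[rowSums(sweep(tails, 2, cc)^2) > 1e-9, ]
  tips <- 0.5 * tails + matrix(0.5 * cc, nrow(tails), 2, byrow = TRUE)
  fc <- field_convergence_point(field_samples(tails, tips))
  expect_equal(fc$point, cc, tolerance = 1e-10)
  expect_lt(fc$residual, 1e-10)

  # two perpendicular lines crossing at p
  p <- c(0.5, 0.25)
  s2 <- field_samples(rbind(p + c(-1, 0), p + c(0, -1)),
                      rbind(p + c(1, 0), p + c(0, 1)))
  expect_equal(field_convergence_point(s2)$point, p, tolerance = 1e-12)

  # parallel vectors are rejected
  s3 <- field_samples(rbind(c(0, 0), c(0, 1)), rbind(c(1, 0), c(1, 1)))
  expect_error(field_convergence_point(s3), "parallel")

  # cross-method agreement on a noisy affine scene
  af <- affine_field_samples(49)
  noisy <- field_samples(af$samples$tails,
                         af$samples$tips + matrix(rnorm(2 * nrow(af$samples$tips),
                                                        0, 0.01), ncol = 2))
  fit <- fit_affine12(color_pairs(noisy$tails, noisy$tips))
  afp <- affine_fixed_point(fit)$point
  fcp <- field_convergence_point(noisy)$point
  expect_lt(sqrt(sum((afp - af$p_star)^2)), 0.05)
  expect_lt(sqrt(sum((fcp - af$p_star)^2)), 0.05)
})

test_that("projection planes select the stated axis pairs", {
  s <- field_samples(matrix(1:12, 4, 3), matrix(13:24, 4, 3), space = "MBDKL")
  rgby <- project_field(s, c(1, 2))
  byld <- project_field(s, c(2, 3))
  expect_equal(rgby$tails, s$tails[, 1:2])
  expect_equal(byld$tails, s$tails[, 2:3])
})
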