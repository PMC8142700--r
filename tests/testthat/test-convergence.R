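random_pairs <- function(seed, n = 120L, D = 3L, sigma = 0.02) {
  set.seed(seed)
  a <- matrix(runif(n * D, 0, 1), n, D)
  M <- diag(runif(D, 0.3, 0.7)) + matrix(runif(D * D, -0.1, 0.1), D, D)
  t0 <- runif(D, -0.2, 0.2)
  b <- a %*% t(M) + matrix(t0, n, D, byrow = TRUE) +
    matrix(rnorm(n * D, 0, sigma), n, D)
  list(pairs = color_pairs(a, b), M = M, t = t0)
}

test_that("build_pairs pairs pixels through the mask in scan order", {
  img <- random_rgb_image(1, 6, 6)
  mask <- matrix(FALSE, 6, 6); mask[c(2, 9, 30)] <- TRUE
  pr <- build_pairs(img, img, mask, space = "linearRGB", cal = test_cal)
  expect_equal(pr$a, pr$b)
  expect_equal(nrow(pr$a), 3L)
  expect_equal(pr$a, pixel_matrix(img)[c(2, 9, 30), ])

  img2 <- random_rgb_image(2, 6, 6)
  expect_error(build_pairs(img, random_rgb_image(3, 5, 5), mask), "sizes differ")

  # exclusion arithmetic
  obj <- matrix(TRUE, 6, 6)
  dark <- dark_pixel_mask(img2, obj, fraction = 0.4, cal = test_cal)
  pr2 <- build_pairs(img, img2, obj, space = "LMS", exclude = list(dark),
                     cal = test_cal)
  expect_equal(nrow(pr2$a), sum(obj & !dark))
  expect_error(build_pairs(img, img2, obj, exclude = list(obj)), "no pixels")
})

test_that("isoluminant pairs drop to D = 2", {
  img <- random_rgb_image(4, 5, 5)
  img2 <- random_rgb_image(5, 5, 5)
  mask <- matrix(TRUE, 5, 5)
  for (space in c("MBDKL", "LAB")) {
    pr <- build_pairs(img, img2, mask, space = space, isoluminant = TRUE,
                      cal = test_cal)
    expect_equal(pr$dims, 2L)
    full <- build_pairs(img, img2, mask, space = space, cal = test_cal)
    keep <- if (space == "MBDKL") 1:2 else 2:3
    expect_equal(pr$a, full$a[, keep])
  }
})

test_that("fit_affine12 recovers exact generating parameters", {
  set.seed(20)
  a <- matrix(runif(1500), 500, 3)
  M0 <- matrix(c(0.5, 0.1, 0, -0.05, 0.6, 0.02, 0.03, 0, 0.4), 3, 3)
  t0 <- c(0.1, -0.05, 0.2)
  b <- a %*% t(M0) + matrix(t0, 500, 3, byrow = TRUE)
  fit <- fit_affine12(color_pairs(a, b))
  expect_lt(max(abs(fit$M - M0)), 1e-8)
  expect_lt(max(abs(fit$t - t0)), 1e-8)
  expect_gte(fit$rrpe, 0.9999)

  # identity data: zero baseline, RRPE undefined
  expect_error(fit_affine12(color_pairs(a, a)), "degenerate baseline")

  # pure translation
  b2 <- sweep(a, 2, c(0.2, 0.1, -0.1), "+")
  fit2 <- fit_affine12(color_pairs(a, b2))
  expect_lt(max(abs(fit2$M - diag(3))), 1e-10)
  expect_lt(fit2$rmse_model, 1e-12)

  # rank deficiency warns and still returns a finite fit
  a3 <- cbind(a[, 1], a[, 1], a[, 2])
  expect_warning(fit3 <- fit_affine12(color_pairs(a3, a3 * 0.5 + 0.1)),
                 "rank-deficient")
  expect_true(all(is.finite(fit3$M)))

  expect_error(fit_affine12(color_pairs(a[1:3, ], b[1:3, ])), "more pairs")
})

test_that("fit_affine4 recovers scale and translation; families nest", {
  set.seed(21)
  a <- matrix(runif(900), 300, 3)
  b <- 0.68 * a
  fit <- fit_affine4(color_pairs(a, b))
  expect_equal(fit$beta, 0.68, tolerance = 1e-10)
  expect_lt(max(abs(fit$t)), 1e-10)

  t0 <- c(0.05, 0.1, -0.02)
  b2 <- 0.4 * a + matrix(t0, 300, 3, byrow = TRUE)
  fit2 <- fit_affine4(color_pairs(a, b2))
  expect_lt(abs(fit2$beta - 0.4), 1e-8)
  expect_lt(max(abs(fit2$t - t0)), 1e-8)
  expect_gte(fit2$rrpe, 0.9999)

  # nesting: data from a non-uniform diagonal map
  b3 <- a %*% diag(c(0.3, 0.6, 0.9))
  p3 <- color_pairs(a, b3)
  expect_gte(fit_affine4(p3)$rmse_model, fit_affine12(p3)$rmse_model - 1e-12)
})

test_that("simplex mode approaches but never beats the closed form", {
  for (s in 1:5) {
    rp <- random_pairs(s, n = 60)
    cf12 <- fit_affine12(rp$pairs)
    sx12 <- fit_affine12(rp$pairs, solver = "simplex", seed = s)
    expect_gte(sx12$rmse_model, cf12$rmse_model - 1e-9)
    cf4 <- fit_affine4(rp$pairs)
    sx4 <- fit_affine4(rp$pairs, solver = "simplex", seed = s)
    expect_gte(sx4$rmse_model, cf4$rmse_model - 1e-9)
    # and it lands close on these well-conditioned problems
    expect_lt(sx4$rmse_model - cf4$rmse_model, 1e-4)
  }
})

test_that("rrpe evaluates its defining ratio and guards zero baselines", {
  expect_equal(rrpe(0, 2), 1)
  expect_equal(rrpe(2, 2), 0)
  expect_equal(rrpe(0.25, 1), 0.75)
  expect_error(rrpe(0.1, 0), "degenerate baseline")
})

test_that("RRPE is at most 1 and non-negative for closed-form fits", {
  for (s in 1:20) {
    rp <- random_pairs(100 + s, n = 50, sigma = 0.1)
    f <- fit_affine12(rp$pairs)
    expect_lte(f$rrpe, 1)
    expect_gte(f$rrpe, 0)
    f4 <- fit_affine4(rp$pairs)
    expect_lte(f4$rrpe, 1)
    expect_gte(f4$rrpe, 0)
  }
})

test_that("affine12 RMSE and RRPE are equivariant under joint rotation", {
  rp <- random_pairs(7, n = 80, sigma = 0.05)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f1 <- fit_affine12(rp$pairs)
  f2 <- fit_affine12(color_pairs(rp$pairs$a %*% t(R), rp$pairs$b %*% t(R)))
  expect_equal(f2$rmse_model, f1$rmse_model, tolerance = 1e-9)
  expect_equal(f2$rrpe, f1$rrpe, tolerance = 1e-9)
})

test_that("parameter recovery under noise is unbiased", {
  set.seed(77)
  M0 <- diag(c(0.5, 0.6, 0.4)); t0 <- c(0.1, 0, -0.1)
  errs <- replicate(100, {
    a <- matrix(runif(450), 150, 3)
    b <- a %*% t(M0) + matrix(t0, 150, 3, byrow = TRUE) +
      matrix(rnorm(450, 0, 0.01), 150, 3)
    fit_affine12(color_pairs(a, b))$M - M0
  })
  expect_lt(max(abs(apply(errs, 1:2, mean))), 1e-3)
})

test_that("fit_over re-parameterises the convex mixture", {
  set.seed(23)
  a <- matrix(runif(300), 100, 3)
  p0 <- c(0.3, 0.4, 0.5)
  b <- 0.5 * a + matrix(0.5 * p0, 100, 3, byrow = TRUE)
  fo <- fit_over(color_pairs(a, b))
  expect_equal(fo$beta, 0.5, tolerance = 1e-10)
  expect_triplet_equal(fo$c_conv, p0, 1e-10)
  expect_true(fo$representable)

  # pure translation: no finite convergence point
  b2 <- sweep(a, 2, c(0.1, 0.1, 0.1), "+")
  fo2 <- fit_over(color_pairs(a, b2))
  expect_false(fo2$representable)
  expect_null(fo2$c_conv)

  # brute-force 1-D refinement over beta agrees on noisy convex data
  b3 <- 0.35 * a + matrix(0.65 * p0, 100, 3, byrow = TRUE) +
    matrix(rnorm(300, 0, 0.01), 100, 3)
  pr3 <- color_pairs(a, b3)
  fo3 <- fit_over(pr3)
  betas <- seq(0.2, 0.6, by = 1e-4)
  rms <- vapply(betas, function(bb) {
    tt <- colMeans(b3) - bb * colMeans(a)
    sqrt(mean(rowSums((sweep(a * bb, 2, tt, "+") - b3)^2)))
  }, numeric(1))
  bstar <- betas[which.min(rms)]
  expect_lt(abs(fo3$beta - bstar), 1e-4)
  expect_lt(max(abs(fo3$c_conv - (colMeans(b3) - bstar * colMeans(a)) / (1 - bstar))),
            1e-2)
})

test_that("converge_report runs the stated factorial", {
  bg <- voronoi_background(40, 20, seed = 31)
  obj <- matrix(FALSE, 40, 40); obj[8:32, 8:32] <- TRUE
  M0 <- diag(c(0.5, 0.55, 0.6)); t0 <- c(0.05, 0.04, 0.03)
  scene <- simulate_affine_scene(bg, obj, M = M0, t = t0)
  tab <- converge_report(scene, cal = test_cal)

  # LMS x isoluminant cells are excluded by construction
  expect_equal(sum(tab$space == "LMS" & tab$isoluminant), 0L)
  # factorial size: LMS gets 2x3x2 cells per family, others 2x3x2x2
  expect_equal(nrow(tab), 2 * (3 * 2 + 2 * 3 * 2 * 2))
  expect_true(all(tab$ok))

  # the affine ground truth is linear in LMS/MBDKL: near-perfect RRPE there
  lin <- tab$space %in% c("LMS", "MBDKL") & !tab$isoluminant &
    tab$family == "affine12"
  expect_true(all(tab$rrpe[lin] >= 0.999))

  # nesting in every cell
  key <- function(d) paste(d$space, d$mask, d$isoluminant, d$dark_excluded)
  t12 <- tab[tab$family == "affine12", ]
  t4 <- tab[tab$family == "affine4", ]
  t4 <- t4[match(key(t12), key(t4)), ]
  expect_true(all(t12$rmse_model <= t4$rmse_model + 1e-9))
})

test_that("converge_report marks failing cells without aborting", {
  bg <- voronoi_background(30, 10, seed = 32)
  obj <- matrix(FALSE, 30, 30); obj[10:20, 10:20] <- TRUE
  scene <- simulate_affine_scene(bg, obj, beta = 1, t = c(0, 0, 0))  # identity
  tab <- converge_report(scene, cal = test_cal)
  expect_true(all(!tab$ok))
  expect_true(all(grepl("degenerate baseline|no pixels", tab$message)))
})
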