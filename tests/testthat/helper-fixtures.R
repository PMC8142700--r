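# Shared fixtures, all built in code.

test_cal <- default_monitor()
test_fund <- cone_fundamentals()
test_grid <- default_wavelength_grid()

# an LMS image holding a filtered region (rows 1..nrow(P)) above an
# unfiltered region, with the matching masks
two_region_lms <- function(P, A) {
  P <- as.matrix(P); A <- as.matrix(A)
  h <- nrow(P) + nrow(A)
  img <- color_image(array(rbind(P, A), c(h, 1L, 3L)), "LMS")
  fm <- matrix(FALSE, h, 1L); fm[seq_len(nrow(P)), 1L] <- TRUE
  list(img = img, filtered = fm, unfiltered = !fm)
}

# a u = 0 scene: the filtered region is an exact per-class scaling of a
# pixel-for-pixel copy of the unfiltered region
u_zero_scene <- function(seed, n = 150L) {
  set.seed(seed)
  A <- matrix(runif(n * 3L, 0.2, 1), n, 3L)
  tau <- runif(3L, 0.3, 0.9)
  c(two_region_lms(sweep(A, 2L, tau, "*"), A), list(tau = tau))
}

# forward-model scene with known (tau, delta) and explicit illuminant;
# channel 2 is forced to be the MSD class
forward_model_scene <- function(seed, n = 400L) {
  set.seed(seed)
  A <- matrix(runif(n * 3L, 0.2, 1), n, 3L)
  A[, 2L] <- A[, 2L] * 1.5
  tau <- runif(3L, 0.3, 0.9)
  delta <- runif(1L, 0.02, 0.15)
  I <- runif(3L, 0.4, 0.8)
  msd <- which.max(apply(A, 2L, function(x) sqrt(mean((x - mean(x))^2))))
  u <- delta * I[msd] * tau[msd] / (1 - delta * I[msd])
  mP <- tau * colMeans(A) + delta * I * (tau + u)
  P <- sweep(sweep(sweep(A, 2L, colMeans(A)), 2L, tau, "*"), 2L, mP, "+")
  c(two_region_lms(P, A), list(tau = tau, delta = delta, I = I, msd = msd))
}

random_rgb_image <- function(seed, h = 8L, w = 8L, lo = 0.05, hi = 0.95) {
  set.seed(seed)
  color_image(array(runif(h * w * 3L, lo, hi), c(h, w, 3L)), "linearRGB")
}

random_lab_image <- function(seed, h = 10L, w = 10L) {
  set.seed(seed)
  color_image(array(c(runif(h * w, 5, 95), runif(h * w, -60, 60),
                      runif(h * w, -60, 60)), c(h, w, 3L)), "LAB")
}

# small glass scene used across tests (64 px keeps the suite fast; the
# generator itself is resolution-independent)
glass_scene <- function(seed, size = 64L, ...) {
  simulate_glass_scene(scene_spec(size = size, n_sites = 25L, seed = seed, ...),
                       cal = test_cal)
}

flat_spectrum <- function(value, grid = test_grid) {
  spectrum(grid, rep(value, length(grid)))
}

expect_triplet_equal <- function(got, want, tol = 1e-12) {
  expect_equal(as.numeric(got), as.numeric(want), tolerance = tol)
}
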