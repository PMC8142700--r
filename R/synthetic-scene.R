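#' Synthetic glass-object scenes
#'
#' The study's stimuli were physically based renders of a hollow glass blob
#' ("Glaven") in a variegated room.  No images were deposited, so this
#' module regenerates the *statistical structure* of such stimuli without a
#' renderer: a seeded Voronoi background with per-cell reflectance spectra,
#' a spectral transmission applied to the light reaching the eye over the
#' object region (two wall passes by default, with a smooth per-pixel
#' path-length exponent field standing in for body-thickness variation),
#' refraction-like spatial displacement, tinted specular highlights, tinted
#' caustics and shadows — each with a ground-truth mask.  Every generator is
#' a pure function of its spec and seed.
#'
#' @name synthetic_scene
NULL

# run code with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# smooth random field in [-1, 1]: a few random low-frequency cosine waves
smooth_field <- function(h, w, n_waves = 4L) {
  xs <- matrix(rep(seq_len(w), each = h), h, w) / w
  ys <- matrix(rep(seq_len(h), times = w), h, w) / h
  f <- matrix(0, h, w)
  for (k in seq_len(n_waves)) {
    fr <- stats::runif(2, 0.5, 3)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + cos(2 * pi * (fr[1] * xs + fr[2] * ys) + ph)
  }
  mx <- max(abs(f))
  if (mx > 0) f / mx else f
}

#' Scene specification
#'
#' Collects everything that determines a synthetic glass scene.  Defaults
#' describe the package's reference stimulus: a 128 x 128 chromatic Voronoi
#' room, two-pass filtering, 1% of the object covered by a body-tinted
#' specular highlight, a tinted caustic and a penumbral shadow below the
#' object, moderate body-thickness variation and a refraction-like
#' displacement of about 2 pixels.
#'
#' @param size image size, `c(H, W)` (each at least 16).
#' @param background `"voronoi"`, `"achromatic_voronoi"`, `"grating"` or
#'   `"uniform"`.
#' @param palette chromatic bias of the background palette:
#'   `"none"`, `"red"`, `"green"`, `"blue"` or `"yellow"`.
#' @param n_sites number of Voronoi sites (at least 2).
#' @param seed integer seed; mandatory for reproducibility.
#' @param illuminant a [spectrum()]; default a warm-white daylight stand-in.
#' @param transmission a [spectrum()] in `[0,1]`; default a blue glass.
#' @param specular_fraction fraction of object pixels covered by the
#'   highlight, in `[0, 0.05]`.
#' @param specular_tint how strongly the highlight is tinged with the body
#'   colour (0 = illuminant colour, 1 = fully filtered), in `[0,1]`.
#' @param caustic_gain gain of the focused tinted light below the object.
#' @param shadow_gain multiplicative attenuation of the shadow region
#'   (1 = no shadow).
#' @param refraction_magnitude displacement-field amplitude in pixels.
#' @param passes number of wall traversals the filtered light makes.
#' @param body_variation amplitude of the smooth per-pixel path-length
#'   exponent field (0 = uniform optical thickness).
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(size = c(128L, 128L),
                       background = c("voronoi", "achromatic_voronoi",
                                      "grating", "uniform"),
                       palette = c("none", "red", "green", "blue", "yellow"),
                       n_sites = 40L, seed,
                       illuminant = default_illuminant("white"),
                       transmission = transmission_bases()$blue,
                       specular_fraction = 0.01, specular_tint = 0.5,
                       caustic_gain = 0.5, shadow_gain = 0.6,
                       refraction_magnitude = 2, passes = 2L,
                       body_variation = 0.25) {
  background <- match.arg(background)
  palette <- match.arg(palette)
  if (missing(seed)) stop("a seed is required (reproducibility)")
  if (length(size) == 1L) size <- c(size, size)
  stopifnot(all(size >= 16L), n_sites >= 2L,
            specular_fraction >= 0, specular_fraction <= 0.05,
            specular_tint >= 0, specular_tint <= 1,
            caustic_gain >= 0, shadow_gain >= 0, refraction_magnitude >= 0,
            passes >= 1L, body_variation >= 0,
            is_spectrum(illuminant), is_spectrum(transmission),
            all(transmission$values >= 0), all(transmission$values <= 1))
  structure(list(size = as.integer(size), background = background,
                 palette = palette, n_sites = as.integer(n_sites),
                 seed = as.integer(seed), illuminant = illuminant,
                 transmission = transmission,
                 effects = list(specular_fraction = specular_fraction,
                                specular_tint = specular_tint,
                                caustic_gain = caustic_gain,
                                shadow_gain = shadow_gain,
                                refraction_magnitude = refraction_magnitude,
                                passes = as.integer(passes),
                                body_variation = body_variation)),
            class = "scene_spec")
}

# ---- bundled stand-in spectra ----------------------------------------------

gauss_spec <- function(grid, mu, sd, amp = 1, base = 0) {
  pmin(pmax(base + amp * exp(-0.5 * ((grid - mu) / sd)^2), 0), 1)
}

#' Stand-in base spectra
#'
#' Smooth synthetic curves substituting for measured paint-chip databases
#' (which are external data); all values lie in `[0, 1]`.
#'
#' `transmission_bases()` emulates the *low-chroma* chips used as glass
#' body colours (nominally 2.5R 7/2, 5G 2.5/2, 5B 4/1, 10Y 5/1): broadband
#' reflectance at the level implied by the chip's Munsell value, with a
#' modest chromatic bump — desaturated, realistic glass tints rather than
#' narrow-band filters.
#'
#' `flat_filter_bases()` emulates the *saturated* chips spanning the
#' flat-filter matching gamut (nominal chroma 8-12): pronounced spectral
#' modulation, normalized to a maximum of exactly 1 as required by
#' [filter_transmission()].
#'
#' @param grid wavelength grid (nm).
#' @return Named list of four [spectrum()]s: red, green, blue, yellow.
#' @export
transmission_bases <- function(grid = default_wavelength_grid()) {
  list(red    = spectrum(grid, gauss_spec(grid, 630, 60, 0.18, 0.36), bounded = TRUE),
       green  = spectrum(grid, gauss_spec(grid, 535, 50, 0.04, 0.045), bounded = TRUE),
       blue   = spectrum(grid, gauss_spec(grid, 465, 45, 0.07, 0.095), bounded = TRUE),
       yellow = spectrum(grid, gauss_spec(grid, 580, 65, 0.09, 0.16), bounded = TRUE))
}

#' @rdname transmission_bases
#' @export
flat_filter_bases <- function(grid = default_wavelength_grid()) {
  shapes <- list(red    = gauss_spec(grid, 630, 50, 0.85, 0.1),
                 green  = gauss_spec(grid, 535, 45, 0.85, 0.1),
                 blue   = gauss_spec(grid, 465, 40, 0.85, 0.1),
                 yellow = gauss_spec(grid, 580, 55, 0.85, 0.1))
  lapply(shapes, function(v) spectrum(grid, v / max(v), bounded = TRUE))
}

#' Stand-in illuminants
#'
#' Broadband blue-ish and yellow-ish daylight-locus stand-ins, and the
#' desaturated mixtures used as scene illuminants: each rendered illuminant
#' is one basis scaled to 70% plus 30% of the other, after both are first
#' scaled down by 50% (see [mix_illuminants()]).
#'
#' @param which `"white"` (yellow-weighted mix), `"blue"` (blue-weighted
#'   mix), `"blue_basis"`, `"yellow_basis"` or `"flat"` (unit equal-energy).
#' @param grid wavelength grid (nm).
#' @return A [spectrum()].
#' @export
default_illuminant <- function(which = c("white", "blue", "blue_basis",
                                         "yellow_basis", "flat"),
                               grid = default_wavelength_grid()) {
  which <- match.arg(which)
  blue <- spectrum(grid, gauss_spec(grid, 475, 70, 0.9, 0.15))
  yellow <- spectrum(grid, gauss_spec(grid, 585, 85, 0.9, 0.15))
  switch(which,
         flat = spectrum(grid, rep(1, length(grid))),
         blue_basis = blue,
         yellow_basis = yellow,
         blue = mix_illuminants(blue, yellow),
         white = mix_illuminants(yellow, blue))
}

# ---- spectral mixing operations --------------------------------------------

common_grid <- function(a, b) {
  if (!isTRUE(all.equal(a$wavelengths_nm, b$wavelengths_nm))) {
    stop("spectra are not on a common wavelength grid")
  }
  a$wavelengths_nm
}

#' Mix transmission distributions along red-green and blue-yellow axes
#'
#' `0.5 * ld_scale * ((a_rg * D_red + (1 - a_rg) * D_green) +
#' (a_by * D_blue + (1 - a_by) * D_yellow))`.  The 0.5 factor keeps the
#' result inside the transmission range `[0, 1]` for mixing weights in
#' `[0, 1]`; weights outside that interval (the design explores `[-1, 1]`)
#' may clip, and the clipped fraction of samples is reported in the
#' `"clip_fraction"` attribute.
#'
#' @param alpha_rg,alpha_by mixing weights along the two axes.
#' @param ld_scale light/dark scale; 1 for the lighter body colour, 0.68
#'   for the darker.
#' @param bases named list with `red`, `green`, `blue`, `yellow`
#'   transmission [spectrum()]s on a common grid, each in `[0,1]`.
#' @return A transmission [spectrum()] in `[0, 1]`.
#' @export
mix_transmission <- function(alpha_rg, alpha_by, ld_scale = 1,
                             bases = transmission_bases()) {
  g <- common_grid(bases$red, bases$green)
  common_grid(bases$blue, bases$yellow)
  common_grid(bases$red, bases$blue)
  stopifnot(ld_scale > 0, ld_scale <= 1)
  v <- 0.5 * ld_scale *
    ((alpha_rg * bases$red$values + (1 - alpha_rg) * bases$green$values) +
     (alpha_by * bases$blue$values + (1 - alpha_by) * bases$yellow$values))
  clipped <- mean(v < 0 | v > 1)
  out <- spectrum(g, pmin(pmax(v, 0), 1), bounded = TRUE)
  attr(out, "clip_fraction") <- clipped
  out
}

#' Filter-parameter triple for the flat-filter matching element
#'
#' @param Thickness overall transmittance scale (> 0); larger is more
#'   transmissive.
#' @param NMX,NMY normalized mouse position in `[0, 1]`: 0 is the top-left
#'   of the notional screen, 1 the bottom-right.
#' @return Object of class `filter_params`.
#' @export
filter_params <- function(Thickness, NMX, NMY) {
  stopifnot(Thickness >= 0, NMX >= 0, NMX <= 1, NMY >= 0, NMY <= 1)
  structure(list(Thickness = Thickness, NMX = NMX, NMY = NMY),
            class = "filter_params")
}

#' Flat-filter transmission from mouse parameters
#'
#' `Thickness * ((NMX * RF + (1 - NMX) * GF) + (NMY * BF + (1 - NMY) * YF))`
#' over four basis transmissions normalized to a maximum of 1.  The
#' thickness factor multiplies the sum of both axis mixtures, so circling
#' the mouse sweeps the filter through all hues at a fixed transmittance.
#' Output is clipped to `[0, 1]` with the clipped fraction reported.
#'
#' @param params a [filter_params()].
#' @param bases named list `red`, `green`, `blue`, `yellow` of normalized
#'   transmission [spectrum()]s (max = 1) on a common grid.
#' @return A transmission [spectrum()].
#' @export
filter_transmission <- function(params, bases = flat_filter_bases()) {
  g <- common_grid(bases$red, bases$green)
  common_grid(bases$blue, bases$yellow)
  common_grid(bases$red, bases$blue)
  v <- params$Thickness *
    ((params$NMX * bases$red$values + (1 - params$NMX) * bases$green$values) +
     (params$NMY * bases$blue$values + (1 - params$NMY) * bases$yellow$values))
  clipped <- mean(v < 0 | v > 1)
  out <- spectrum(g, pmin(pmax(v, 0), 1), bounded = TRUE)
  attr(out, "clip_fraction") <- clipped
  out
}

#' Desaturating illuminant mixture
#'
#' Both inputs are first scaled by `prescale` (default 50%, preventing
#' highlight burn-out), then combined as `w * spd_a + (1 - w) * spd_b`
#' (default 70/30, slightly desaturating each illuminant toward the other).
#'
#' @param spd_a,spd_b illuminant [spectrum()]s on a common grid.
#' @param w mixing weight of `spd_a`.
#' @param prescale pre-mixing intensity scale applied to both.
#' @return A [spectrum()].
#' @export
mix_illuminants <- function(spd_a, spd_b, w = 0.7, prescale = 0.5) {
  g <- common_grid(spd_a, spd_b)
  spectrum(g, prescale * (w * spd_a$values + (1 - w) * spd_b$values))
}

# ---- Voronoi backgrounds ----------------------------------------------------

# nearest-site assignment for every pixel; returns H x W integer matrix
voronoi_cells <- function(h, w, sites) {
  xs <- rep(seq_len(w), each = h)
  ys <- rep(seq_len(h), times = w)
  d2 <- outer(xs, sites[, 1], "-")^2 + outer(ys, sites[, 2], "-")^2
  matrix(max.col(-d2, ties.method = "first"), h, w)
}

palette_bias_vec <- function(palette) {
  switch(palette,
         none = c(0, 0, 0),
         red = c(0.25, -0.05, -0.05),
         green = c(-0.05, 0.25, -0.05),
         blue = c(-0.05, -0.05, 0.25),
         yellow = c(0.18, 0.18, -0.1))
}

#' Seeded Voronoi background texture
#'
#' Nearest-site tessellation with one colour per cell, drawn from a seeded
#' palette with an optional chromatic bias.  The achromatic variant emits
#' `R = G = B` per cell.  Deterministic given the seed.
#'
#' @param size `c(H, W)` or a single side length.
#' @param n_sites number of sites (at least 2).
#' @param palette chromatic bias (see [scene_spec()]).
#' @param achromatic produce shades of gray only?
#' @param seed integer seed.
#' @return A [color_image()] in linear RGB.
#' @export
voronoi_background <- function(size = c(128L, 128L), n_sites = 40L,
                               palette = "none", achromatic = FALSE, seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_sites < 2L) stop("n_sites must be at least 2")
  if (length(size) == 1L) size <- c(size, size)
  h <- size[1]; w <- size[2]
  with_seed(seed, {
    sites <- cbind(stats::runif(n_sites, 1, w), stats::runif(n_sites, 1, h))
    cells <- voronoi_cells(h, w, sites)
    cols <- if (achromatic) {
      g <- stats::runif(n_sites, 0.1, 0.9)
      cbind(g, g, g)
    } else {
      bias <- palette_bias_vec(palette)
      c0 <- matrix(stats::runif(3 * n_sites, 0.1, 0.9), n_sites, 3)
      pmin(pmax(sweep(c0, 2L, bias, "+"), 0.02), 0.98)
    }
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) img[, , ch] <- matrix(cols[cells, ch], h, w)
    out <- color_image(img, "linearRGB")
    attr(out, "sites") <- sites
    attr(out, "cells") <- cells
    out
  })
}

# blob object mask: perturbed superellipse; returns logical H x W
blob_mask <- function(h, w, radius_frac = 0.3, n_harmonics = 4L) {
  cx <- w / 2; cy <- h / 2
  r0 <- radius_frac * min(h, w)
  amp <- stats::runif(n_harmonics, 0, 0.12)
  ph <- stats::runif(n_harmonics, 0, 2 * pi)
  xs <- matrix(rep(seq_len(w), each = h), h, w) - cx
  ys <- matrix(rep(seq_len(h), times = w), h, w) - cy
  th <- atan2(ys, xs)
  rr <- sqrt(xs^2 + ys^2)
  rmod <- r0 * (1 + Reduce(`+`, lapply(seq_len(n_harmonics), function(k) {
    amp[k] * cos(k * th + ph[k])
  })))
  rr <= rmod
}

disk_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

# ---- scene generators -------------------------------------------------------

new_scene <- function(unfiltered, filtered, masks, truth, spec = NULL) {
  stopifnot(all(dim(unfiltered) == dim(filtered)))
  h <- dim(unfiltered)[1]; w <- dim(unfiltered)[2]
  empty <- matrix(FALSE, h, w)
  for (nm in c("object", "highlight", "caustic", "shadow")) {
    if (is.null(masks[[nm]])) masks[[nm]] <- empty
  }
  stopifnot(!any(masks$highlight & !masks$object),
            !any(masks$caustic & masks$object),
            !any(masks$shadow & masks$object))
  structure(list(unfiltered = unfiltered, filtered = filtered,
                 masks = masks, truth = truth, spec = spec),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  d <- dim(x$unfiltered)
  cat(sprintf("<synthetic_scene %dx%d: object %d px, highlight %d, caustic %d, shadow %d>\n",
              d[1], d[2], sum(x$masks$object), sum(x$masks$highlight),
              sum(x$masks$caustic), sum(x$masks$shadow)))
  invisible(x)
}

#' Exact affine scene (oracle generator)
#'
#' Applies a known affine colour transform (plus optional seeded Gaussian
#' noise) to the background inside the object mask and records the ground
#' truth — a closed-loop oracle for the convergence fitters.
#'
#' @param background a linear RGB [color_image()].
#' @param object_mask logical object mask.
#' @param M 3x3 matrix, or `NULL` when `beta` is given.
#' @param beta uniform scaling factor (used when `M` is `NULL`).
#' @param t translation triplet.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed noise seed.
#' @return A `synthetic_scene` with `truth$M`, `truth$beta`, `truth$t`.
#' @export
simulate_affine_scene <- function(background, object_mask, M = NULL, beta = NULL,
                                  t = c(0, 0, 0), noise_sigma = 0, seed = 1L) {
  stopifnot(image_space(background) == "linearRGB")
  check_mask_for(object_mask, background)
  if (is.null(M) && is.null(beta)) stop("supply M or beta")
  p <- pixel_matrix(background)
  sel <- as.vector(object_mask)
  a <- p[sel, , drop = FALSE]
  b <- if (!is.null(M)) a %*% t(M) else a * beta
  b <- sweep(b, 2L, t, "+")
  if (noise_sigma > 0) {
    b <- b + with_seed(seed, matrix(stats::rnorm(length(b), 0, noise_sigma),
                                    nrow(b), 3L))
  }
  p[sel, ] <- b
  new_scene(background, matrix_to_image(p, dim(background), "linearRGB"),
            masks = list(object = object_mask),
            truth = list(M = M, beta = beta, t = t, noise_sigma = noise_sigma,
                         seed = seed))
}

#' Simulate a glass-object scene
#'
#' Builds the unfiltered room, then the same room seen with the transparent
#' object added.  Inside the object the light reaching the eye is the
#' (refraction-displaced) background radiance multiplied by
#' `transmission^(passes * e(x, y))`, where `e` is a smooth seeded exponent
#' field emulating optical-path variation over the curved body.  Specular
#' highlight pixels add a bright reflection of the illuminant mixed toward
#' the body tint; caustic pixels below the object gain focused tinted
#' light; shadow pixels are attenuated.  All masks and generating
#' parameters are recorded, and the output is a pure function of the spec.
#'
#' @param spec a [scene_spec()].
#' @param cal monitor model used to express radiance as linear RGB.
#' @param fundamentals cone fundamentals.
#' @return A `synthetic_scene`.
#' @export
simulate_glass_scene <- function(spec, cal = default_monitor(),
                                 fundamentals = cone_fundamentals(cal$grid)) {
  stopifnot(inherits(spec, "scene_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  grid <- cal$grid
  dl <- mean(diff(grid))
  sens <- vapply(fundamentals, resample_spectrum, numeric(length(grid)), grid = grid)
  Iv <- resample_spectrum(spec$illuminant, grid)
  Tv <- resample_spectrum(spec$transmission, grid)
  lms_rgb <- solve(calibration_to_lms_matrix(cal, fundamentals))
  eff <- spec$effects

  with_seed(spec$seed, {
    # background reflectances
    if (spec$background %in% c("voronoi", "achromatic_voronoi")) {
      sites <- cbind(stats::runif(spec$n_sites, 1, w),
                     stats::runif(spec$n_sites, 1, h))
      cells <- voronoi_cells(h, w, sites)
      refl <- background_reflectances(spec, grid)
    } else {
      cells <- matrix(seq_len(h * w), h, w)   # one "cell" per pixel
      g <- if (spec$background == "grating") {
        xs <- matrix(rep(seq_len(w), each = h), h, w)
        0.5 + 0.4 * sin(2 * pi * 3 * xs / w)
      } else {
        matrix(0.7, h, w)
      }
      refl <- outer(as.vector(g), rep(1, length(grid)))
    }

    # per-cell unfiltered radiance -> LMS -> RGB
    lms_cell <- (refl %*% (sens * Iv)) * dl
    unfilt_px <- lms_cell[as.vector(cells), , drop = FALSE] %*% t(lms_rgb)
    unfiltered <- matrix_to_image(unfilt_px, c(h, w), "linearRGB")

    # geometry
    object <- blob_mask(h, w)
    obj_idx <- which(object)
    n_obj <- length(obj_idx)
    cx <- mean(col(object)[obj_idx]); cy <- mean(row(object)[obj_idx])
    r_obj <- sqrt(n_obj / pi)

    highlight <- matrix(FALSE, h, w)
    if (eff$specular_fraction > 0) {
      r_hl <- sqrt(eff$specular_fraction * n_obj / pi)
      highlight <- disk_mask(h, w, cx + 0.45 * r_obj, cy - 0.45 * r_obj, r_hl) & object
    }
    caustic <- disk_mask(h, w, cx + 0.3 * r_obj, cy + 1.45 * r_obj, 0.45 * r_obj) & !object
    shadow <- disk_mask(h, w, cx - 0.3 * r_obj, cy + 1.5 * r_obj, 0.6 * r_obj) &
      !object & !caustic

    # refraction-like displacement of the sampled background
    src_cells <- cells
    if (eff$refraction_magnitude > 0) {
      dx <- eff$refraction_magnitude * smooth_field(h, w)
      dy <- eff$refraction_magnitude * smooth_field(h, w)
      ii <- row(cells)[obj_idx]; jj <- col(cells)[obj_idx]
      si <- pmin(pmax(round(ii + dy[obj_idx]), 1L), h)
      sj <- pmin(pmax(round(jj + dx[obj_idx]), 1L), w)
      src_cells[obj_idx] <- cells[cbind(si, sj)]
      displacement_summary <- list(magnitude = eff$refraction_magnitude,
                                   mean_abs_dx = mean(abs(dx[obj_idx])),
                                   mean_abs_dy = mean(abs(dy[obj_idx])))
    } else {
      displacement_summary <- list(magnitude = 0)
    }

    # per-pixel path-length exponent over the object
    e_field <- 1 + eff$body_variation * smooth_field(h, w)

    # filtered radiance over the object: refl * I * T^(passes * e)
    robj <- refl[src_cells[obj_idx], , drop = FALSE]
    expo <- eff$passes * e_field[obj_idx]
    logT <- log(pmax(Tv, 1e-12))
    Tpow <- exp(outer(expo, logT))          # n_obj x n_bands
    rad <- robj * Tpow
    lms_obj <- (rad %*% (sens * Iv)) * dl

    # tinted specular highlight: bright illuminant reflection mixed toward
    # the body colour (total internal reflection tints the inner highlight)
    if (any(highlight)) {
      spec_spd <- (1 - eff$specular_tint) * Iv + eff$specular_tint * Iv * Tv
      lms_spec <- as.numeric(crossprod(sens, spec_spd)) * dl
      lum_un <- rowSums(lms_cell[as.vector(cells), , drop = FALSE])
      gain_h <- 1.5 * max(lum_un) / sum(lms_spec)
      hl_in_obj <- highlight[obj_idx]
      lms_obj[hl_in_obj, ] <- lms_obj[hl_in_obj, , drop = FALSE] +
        matrix(gain_h * lms_spec, sum(hl_in_obj), 3L, byrow = TRUE)
    }

    filt_px <- unfilt_px
    filt_px[obj_idx, ] <- lms_obj %*% t(lms_rgb)

    # caustic: focused light below the object, tinted by the transmission
    if (eff$caustic_gain > 0 && any(caustic)) {
      lms_c <- as.numeric(crossprod(sens, Iv * Tv)) * dl
      rgb_c <- as.numeric(lms_rgb %*% lms_c)
      ci <- which(caustic)
      filt_px[ci, ] <- filt_px[ci, , drop = FALSE] +
        matrix(eff$caustic_gain * rgb_c, length(ci), 3L, byrow = TRUE)
    }
    if (eff$shadow_gain != 1 && any(shadow)) {
      si <- which(shadow)
      filt_px[si, ] <- filt_px[si, , drop = FALSE] * eff$shadow_gain
    }

    filtered <- matrix_to_image(filt_px, c(h, w), "linearRGB")
    new_scene(unfiltered, filtered,
              masks = list(object = object, highlight = highlight,
                           caustic = caustic, shadow = shadow),
              truth = list(transmission = spec$transmission,
                           illuminant = spec$illuminant,
                           displacement = displacement_summary,
                           effects = eff, seed = spec$seed),
              spec = spec)
  })
}

# per-cell reflectance spectra for voronoi backgrounds: seeded combinations
# of the four chromatic bases plus a neutral base, clipped to [0, 1]
background_reflectances <- function(spec, grid) {
  bases <- transmission_bases(grid)
  B <- cbind(bases$red$values, bases$green$values, bases$blue$values,
             bases$yellow$values, rep(1, length(grid)))
  n <- spec$n_sites
  if (spec$background == "achromatic_voronoi") {
    g <- stats::runif(n, 0.1, 0.9)
    return(outer(g, rep(1, length(grid))))
  }
  wgt <- matrix(stats::runif(n * 4L, 0, 0.8), n, 4L)
  bias_idx <- match(spec$palette, c("red", "green", "blue", "yellow"))
  if (!is.na(bias_idx)) wgt[, bias_idx] <- wgt[, bias_idx] + 0.5
  wgt <- cbind(wgt, stats::runif(n, 0.05, 0.3))
  pmin(pmax(wgt %*% t(B), 0.02), 0.98)
}

#' Render the flat-filter matching element
#'
#' A deliberately simplified flat-filter model: inside a centred disk each
#' pixel's achromatic reflectance is seen through
#' `transmission^passes` under the illuminant; outside the disk the
#' background is seen directly.  This is a stated simplification of the
#' physically derived filter equations in the flat-filter literature, whose
#' exact published form is external to this package.
#'
#' @param background an achromatic linear RGB [color_image()] whose gray
#'   values are read as reflectances.
#' @param transmission a transmission [spectrum()] in `[0,1]`.
#' @param illuminant an illuminant [spectrum()].
#' @param region disk spec: list with `cx`, `cy`, `r` (pixels); default a
#'   centred disk of radius 0.23 x min(H, W).
#' @param passes number of filter traversals (default 2).
#' @param cal,fundamentals colorimetry configuration.
#' @return A linear RGB [color_image()] with attribute `disk_mask`.
#' @export
render_flat_filter <- function(background, transmission, illuminant,
                               region = NULL, passes = 2L,
                               cal = default_monitor(),
                               fundamentals = cone_fundamentals(cal$grid)) {
  stopifnot(image_space(background) == "linearRGB")
  p <- pixel_matrix(background)
  if (max(abs(p[, 1] - p[, 2]), abs(p[, 2] - p[, 3])) > 1e-9) {
    stop("flat-filter background must be achromatic")
  }
  h <- dim(background)[1]; w <- dim(background)[2]
  if (is.null(region)) region <- list(cx = w / 2, cy = h / 2, r = 0.23 * min(h, w))
  if (region$cx - region$r < 1 || region$cx + region$r > w ||
      region$cy - region$r < 1 || region$cy + region$r > h) {
    stop("filter disk extends outside the image")
  }
  grid <- cal$grid
  dl <- mean(diff(grid))
  sens <- vapply(fundamentals, resample_spectrum, numeric(length(grid)), grid = grid)
  Iv <- resample_spectrum(illuminant, grid)
  Tv <- resample_spectrum(transmission, grid)
  lms_rgb <- solve(calibration_to_lms_matrix(cal, fundamentals))
  lms_I <- as.numeric(crossprod(sens, Iv)) * dl
  lms_IT <- as.numeric(crossprod(sens, Iv * Tv^passes)) * dl
  g <- p[, 1]                       # achromatic reflectance per pixel
  disk <- disk_mask(h, w, region$cx, region$cy, region$r)
  out <- outer(g, as.numeric(lms_rgb %*% lms_I))
  dv <- as.vector(disk)
  out[dv, ] <- outer(g[dv], as.numeric(lms_rgb %*% lms_IT))
  img <- matrix_to_image(out, c(h, w), "linearRGB")
  attr(img, "disk_mask") <- disk
  img
}

#' Bundle the flat-filter element configuration
#'
#' Everything [find_best_matching_filter()] needs to render candidate
#' matching elements: the achromatic background, normalized bases, the
#' illuminant, disk geometry, pass count and colorimetry.
#'
#' @param size element image size (default 64).
#' @param seed seed for the achromatic Voronoi background.
#' @param illuminant illuminant [spectrum()].
#' @param bases normalized transmission bases.
#' @param passes filter traversals.
#' @param cal,fundamentals colorimetry configuration.
#' @return List consumed by [find_best_matching_filter()].
#' @export
flat_filter_element_spec <- function(size = 64L, seed = 1L,
                                     illuminant = default_illuminant("white"),
                                     bases = flat_filter_bases(),
                                     passes = 2L, cal = default_monitor(),
                                     fundamentals = cone_fundamentals(cal$grid)) {
  bg <- voronoi_background(size, n_sites = 25L, achromatic = TRUE, seed = seed)
  list(background = bg, bases = bases, illuminant = illuminant,
       region = NULL, passes = passes, cal = cal, fundamentals = fundamentals)
}
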