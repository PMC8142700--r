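#' Region-ratio statistics between filtered and unfiltered image regions
#'
#' The three competing descriptors of a transparent layer's colour code:
#'
#' * `rmc()` — ratio of mean cone excitations, per cone class, with the
#'   filtered region in the numerator;
#' * `rsd()` — ratio of standard deviations of cone excitations;
#' * `robust_ratio()` — an estimator of the three-component colour code
#'   `tau` that corrects the mean ratio for illuminant and direct-reflection
#'   contributions through intermediate quantities `u`, `v` and `delta`.
#'
#' Standard deviations use the population form (divide by N) by default;
#' set `sd_type = "sample"` to divide by N - 1 (the choice is immaterial for
#' regions of realistic size but must be pinned for reproducibility).
#'
#' @param img a [color_image()] in LMS.
#' @param filtered,unfiltered logical H x W masks; non-empty and disjoint.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return `rmc()`/`rsd()` return a `cone_ratio` object: numeric triplet
#'   (L, M, S) with a `statistic` attribute.
#' @export
rmc <- function(img, filtered, unfiltered) {
  P <- region_pixels(img, filtered, unfiltered)
  den <- colMeans(P$A)
  check_denominator(den, "mean")
  new_cone_ratio(colMeans(P$P) / den, "RMC")
}

#' @rdname rmc
#' @export
rsd <- function(img, filtered, unfiltered, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  P <- region_pixels(img, filtered, unfiltered)
  den <- apply(P$A, 2L, sd_of, sd_type)
  check_denominator(den, "standard deviation")
  new_cone_ratio(apply(P$P, 2L, sd_of, sd_type) / den, "RSD")
}

new_cone_ratio <- function(v, tag) {
  names(v) <- c("L", "M", "S")
  structure(v, statistic = tag, class = "cone_ratio")
}

#' @export
print.cone_ratio <- function(x, ...) {
  cat(sprintf("<%s: L %.4g, M %.4g, S %.4g>\n",
              attr(x, "statistic"), x[1], x[2], x[3]))
  invisible(x)
}

region_pixels <- function(img, filtered, unfiltered) {
  stopifnot(image_space(img) %in% c("LMS", "linearRGB"))
  check_mask_for(filtered, img)
  check_mask_for(unfiltered, img)
  if (any(filtered & unfiltered)) stop("filtered and unfiltered masks overlap")
  list(P = pixel_matrix(img, filtered), A = pixel_matrix(img, unfiltered))
}

check_denominator <- function(den, what) {
  bad <- which(den == 0)
  if (length(bad)) {
    stop(sprintf("unfiltered %s is zero for cone class %s",
                 what, paste(c("L", "M", "S")[bad], collapse = ", ")))
  }
}

sd_of <- function(x, type = "population") {
  if (type == "population") sqrt(mean((x - mean(x))^2)) else stats::sd(x)
}

#' Complement-of-object unfiltered region
#'
#' The unfiltered region defaults to everything outside the object mask,
#' optionally shrunk by a border margin around the object to guard against
#' refraction contamination at the object's edge.
#'
#' @param object logical H x W object mask.
#' @param margin number of pixels of chessboard-distance margin to exclude
#'   around the object (default 0).
#' @return A [region_mask()].
#' @export
background_mask <- function(object, margin = 0L) {
  out <- !object
  if (margin > 0L) {
    grown <- object
    for (i in seq_len(margin)) grown <- dilate1(grown)
    out <- out & !grown
  }
  region_mask(out, "custom")
}

# one step of 8-neighbour dilation
dilate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  out <- m
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    src <- m[pmin(pmax(seq_len(h) + di, 1L), h), pmin(pmax(seq_len(w) + dj, 1L), w)]
    out <- out | src
  }
  out
}

#' Illuminant estimate from the unfiltered background
#'
#' The component-wise mean of the unfiltered background colours — the
#' package's stand-in for the unknown scene illuminant.
#'
#' @param img a [color_image()] in LMS.
#' @param unfiltered non-empty logical mask.
#' @return LMS triplet.
#' @export
estimate_illuminant <- function(img, unfiltered) {
  check_mask_for(unfiltered, img)
  stats::setNames(colMeans(pixel_matrix(img, unfiltered)), c("L", "M", "S"))
}

#' @rdname rmc
#' @param illuminant `"estimate"` (default; uses [estimate_illuminant()]) or
#'   an explicit LMS triplet.
#' @details
#' `robust_ratio()` first finds the cone class with the largest background
#' standard deviation (the MSD class) and computes
#' `tau_MSD = sd(P_MSD)/sd(A_MSD)`,
#' `u = mean(P_MSD) - tau_MSD * mean(A_MSD)`,
#' `v = (tau_MSD + u) * I_MSD`, `delta = u/v`, and finally
#' `tau_i = (mean(P_i) - u*delta*I_i) / (mean(A_i) + delta*I_i)` for all
#' three classes.  The general formula reproduces `tau_MSD` exactly in the
#' MSD channel (an algebraic identity), and when `u = 0` the whole triplet
#' collapses to the RMC.
#' @return `robust_ratio()` returns a `robust_ratio` object: list with
#'   fields `tau`, `u`, `v`, `delta`, `msd_channel`, `illuminant_estimate`.
#' @export
robust_ratio <- function(img, filtered, unfiltered, illuminant = "estimate",
                         sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  R <- region_pixels(img, filtered, unfiltered)
  I <- if (identical(illuminant, "estimate")) {
    estimate_illuminant(img, unfiltered)
  } else {
    stopifnot(is.numeric(illuminant), length(illuminant) == 3L)
    stats::setNames(as.numeric(illuminant), c("L", "M", "S"))
  }
  sdA <- apply(R$A, 2L, sd_of, sd_type)
  msd <- which.max(sdA)
  if (sdA[msd] == 0) stop("background is constant in every cone class")
  tau_msd <- sd_of(R$P[, msd], sd_type) / sdA[msd]
  u <- mean(R$P[, msd]) - tau_msd * mean(R$A[, msd])
  v <- (tau_msd + u) * I[msd]
  if (v == 0) stop("degenerate robust-ratio estimate: v = 0")
  delta <- u / v
  tau <- (colMeans(R$P) - u * delta * I) / (colMeans(R$A) + delta * I)
  names(tau) <- c("L", "M", "S")
  structure(list(tau = tau, u = u, v = unname(v), delta = unname(delta),
                 msd_channel = c("L", "M", "S")[msd],
                 illuminant_estimate = I),
            class = "robust_ratio")
}

#' @export
print.robust_ratio <- function(x, ...) {
  cat(sprintf("<robust_ratio: tau = (%.4g, %.4g, %.4g), u %.4g, delta %.4g, MSD %s>\n",
              x$tau[1], x$tau[2], x$tau[3], x$u, x$delta, x$msd_channel))
  invisible(x)
}

#' Dark-pixel exclusion mask
#'
#' Marks object pixels whose luminance falls below `fraction` times the
#' maximum luminance over the object (specular highlights excluded when
#' computing that maximum).  The returned mask selects pixels to EXCLUDE.
#'
#' @param img a [color_image()] (linear RGB, LMS or XYZ).
#' @param object logical object mask (non-empty).
#' @param highlights logical highlight mask (may be all-`FALSE`).
#' @param fraction luminance threshold as a fraction of the maximum
#'   (default 0.05).
#' @param cal calibration used to derive luminance from linear RGB.
#' @return A [region_mask()] labelled `"dark"`.
#' @export
dark_pixel_mask <- function(img, object, highlights = NULL, fraction = 0.05,
                            cal = default_monitor()) {
  check_mask_for(object, img)
  stopifnot(fraction > 0, fraction < 1)
  if (is.null(highlights)) highlights <- matrix(FALSE, nrow(object), ncol(object))
  ref_region <- object & !highlights
  if (!any(ref_region)) stop("object lies entirely inside the highlight mask")
  lum <- luminance_map(img, cal)
  thr <- fraction * max(lum[ref_region])
  region_mask(object & (lum < thr), "dark")
}

#' Search the flat-filter gamut for the best-matching statistic
#'
#' Exhaustively renders the flat-filter matching element over a grid of
#' `(Thickness, NMX, NMY)` parameters, computes the requested region
#' statistic for each rendering, and returns the parameter triple whose
#' statistic is closest (Euclidean distance) to the target.  Ties keep the
#' first candidate in lexicographic grid order (Thickness varying slowest,
#' then NMX, then NMY).
#'
#' @param target a `cone_ratio`, a `robust_ratio`, or a numeric triplet.
#' @param element_spec a [flat_filter_element_spec()].
#' @param grid list with numeric vectors `Thickness`, `NMX`, `NMY`.
#' @param statistic which statistic to match: `"rmc"`, `"rsd"` or `"robust"`.
#' @return List: `params` (named triple), `achieved` (statistic triplet),
#'   `distance`, and the full search `table`.
#' @export
find_best_matching_filter <- function(target, element_spec,
                                      grid = list(Thickness = seq(0.2, 1, by = 0.2),
                                                  NMX = seq(0, 1, by = 0.25),
                                                  NMY = seq(0, 1, by = 0.25)),
                                      statistic = c("rmc", "rsd", "robust")) {
  statistic <- match.arg(statistic)
  tvec <- if (inherits(target, "robust_ratio")) target$tau else as.numeric(target)
  stopifnot(length(tvec) == 3L)
  if (!length(grid$Thickness) || !length(grid$NMX) || !length(grid$NMY)) {
    stop("empty search grid")
  }
  cand <- expand.grid(NMY = grid$NMY, NMX = grid$NMX, Thickness = grid$Thickness,
                      KEEP.OUT.ATTRS = FALSE)[, c("Thickness", "NMX", "NMY")]
  best <- NULL
  dists <- numeric(nrow(cand))
  achieved <- matrix(NA_real_, nrow(cand), 3L)
  for (i in seq_len(nrow(cand))) {
    fp <- filter_params(cand$Thickness[i], cand$NMX[i], cand$NMY[i])
    st <- tryCatch(flat_filter_statistic(fp, element_spec, statistic),
                   error = function(e) {
                     stop(sprintf("flat-filter rendering failed at Thickness=%g NMX=%g NMY=%g: %s",
                                  fp$Thickness, fp$NMX, fp$NMY, conditionMessage(e)))
                   })
    achieved[i, ] <- st
    dists[i] <- sqrt(sum((st - tvec)^2))
    if (is.null(best) || dists[i] < dists[best]) best <- i
  }
  list(params = c(Thickness = cand$Thickness[best], NMX = cand$NMX[best],
                  NMY = cand$NMY[best]),
       achieved = achieved[best, ],
       distance = dists[best],
       table = cbind(cand, distance = dists))
}

# render one flat-filter element and compute the requested LMS statistic
flat_filter_statistic <- function(fp, spec, statistic) {
  el <- render_flat_filter(spec$background, filter_transmission(fp, spec$bases),
                           spec$illuminant, region = spec$region,
                           passes = spec$passes, cal = spec$cal,
                           fundamentals = spec$fundamentals)
  disk <- attr(el, "disk_mask")
  lms <- rgb_to_lms(el, spec$cal, spec$fundamentals)
  st <- switch(statistic,
               rmc = rmc(lms, disk, !disk),
               rsd = rsd(lms, disk, !disk),
               robust = robust_ratio(lms, disk, !disk)$tau)
  as.numeric(st)
}
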