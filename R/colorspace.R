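#' Linear RGB / XYZ conversions via a monitor calibration
#'
#' @param img a [color_image()] in the appropriate source space.
#' @param cal a [monitor_calibration()].
#' @return A [color_image()] in the target space.
#' @export
rgb_to_xyz <- function(img, cal) {
  stopifnot(image_space(img) == "linearRGB")
  m <- calibration_to_matrix(cal)
  matrix_to_image(pixel_matrix(img) %*% t(m), dim(img), "XYZ")
}

#' @rdname rgb_to_xyz
#' @export
xyz_to_rgb <- function(img, cal) {
  stopifnot(image_space(img) == "XYZ")
  m <- solve(calibration_to_matrix(cal))
  matrix_to_image(pixel_matrix(img) %*% t(m), dim(img), "linearRGB")
}

# CIELAB forward nonlinearity, two branches meeting at t = delta^3
lab_f <- function(t) {
  delta <- 6 / 29
  ifelse(t > delta^3, t^(1 / 3), t / (3 * delta^2) + 4 / 29)
}

#' XYZ to CIELAB
#'
#' Standard CIELAB equations with the two-branch `f(t)` and `delta = 6/29`.
#' The reference white is conventionally the maximum white of the monitor,
#' so an RGB of `(1,1,1)` maps to `L* = 100`, `a* = b* = 0`.
#'
#' @param img a [color_image()] in XYZ.
#' @param white XYZ triplet of the reference white; all components positive.
#' @return A [color_image()] in LAB.
#' @export
xyz_to_lab <- function(img, white) {
  stopifnot(image_space(img) == "XYZ", length(white) == 3L)
  if (any(white <= 0)) stop("reference white must have all-positive XYZ")
  p <- pixel_matrix(img)
  fx <- lab_f(p[, 1] / white[1])
  fy <- lab_f(p[, 2] / white[2])
  fz <- lab_f(p[, 3] / white[3])
  matrix_to_image(cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz)),
                  dim(img), "LAB")
}

#' Linear RGB to LMS cone excitations
#'
#' The LMS excitation of a pixel is the linear combination of the three
#' primaries' maximum cone excitations weighted by the pixel's RGB values,
#' e.g. `L = R*L_R + G*L_G + B*L_B`.  The default cone fundamentals are
#' pre-normalized so an equal-energy stimulus of unit intensity excites each
#' cone class by exactly 1.
#'
#' @param img a [color_image()] in linear RGB.
#' @param cal a [monitor_calibration()] carrying primary spectra, or
#'   `lms_matrix` may be given directly.
#' @param fundamentals list of 3 sensitivity [spectrum()]s.
#' @param lms_matrix optional precomputed 3x3 per-primary LMS matrix
#'   (columns R, G, B), bypassing the spectral integration.
#' @return A [color_image()] in LMS.
#' @export
rgb_to_lms <- function(img, cal = default_monitor(),
                       fundamentals = cone_fundamentals(cal$grid),
                       lms_matrix = NULL) {
  stopifnot(image_space(img) == "linearRGB")
  m <- if (is.null(lms_matrix)) calibration_to_lms_matrix(cal, fundamentals) else lms_matrix
  matrix_to_image(pixel_matrix(img) %*% t(m), dim(img), "LMS")
}

#' @rdname rgb_to_lms
#' @export
lms_to_rgb <- function(img, cal = default_monitor(),
                       fundamentals = cone_fundamentals(cal$grid),
                       lms_matrix = NULL) {
  stopifnot(image_space(img) == "LMS")
  m <- if (is.null(lms_matrix)) calibration_to_lms_matrix(cal, fundamentals) else lms_matrix
  matrix_to_image(pixel_matrix(img) %*% t(solve(m)), dim(img), "linearRGB")
}

#' LMS to MB-DKL opponent coordinates
#'
#' Differential opponent coordinates relative to an adapting background:
#' with `D = LMS - background`, axis 1 is the red-green signal `dL - dM`,
#' axis 2 the blue-yellow signal `dS - (dL + dM)` and axis 3 the light-dark
#' signal `dL + dM + dS`.  The background maps to the origin.  By default
#' the axes are left un-rescaled (mechanism-null directions only);
#' `scaling = "unit_contrast"` first divides each cone differential by its
#' background value (cone contrast), one of several conventions in use.
#'
#' @param img a [color_image()] in LMS.
#' @param background LMS triplet of the adapting background; all positive.
#' @param scaling `"none"` (default) or `"unit_contrast"`.
#' @return A [color_image()] in MBDKL.
#' @export
lms_to_mbdkl <- function(img, background, scaling = c("none", "unit_contrast")) {
  scaling <- match.arg(scaling)
  stopifnot(image_space(img) == "LMS", length(background) == 3L)
  if (any(background <= 0)) stop("background LMS must be all-positive")
  p <- sweep(pixel_matrix(img), 2L, as.numeric(background))
  if (scaling == "unit_contrast") p <- sweep(p, 2L, as.numeric(background), "/")
  matrix_to_image(p %*% t(mbdkl_matrix()), dim(img), "MBDKL")
}

#' @rdname lms_to_mbdkl
#' @export
mbdkl_matrix <- function() {
  rbind(rg = c(1, -1, 0), by = c(-1, -1, 1), ld = c(1, 1, 1))
}

#' Project colours into the isoluminant plane
#'
#' Drops the light-dark component: MB-DKL axis 3, or L* for CIELAB.  The two
#' retained components are unchanged.
#'
#' @param img a [color_image()] in MBDKL or LAB, or an N x 3 matrix with a
#'   `space` argument.
#' @param space space tag when `img` is a plain matrix.
#' @return H x W x 2 array (or N x 2 matrix) of chromatic coordinates.
#' @export
project_isoluminant <- function(img, space = image_space(img)) {
  keep <- switch(space,
                 MBDKL = c(1L, 2L),
                 LAB = c(2L, 3L),
                 stop("isoluminant projection is defined for MBDKL and LAB only"))
  if (inherits(img, "color_image") || (is.array(img) && length(dim(img)) == 3L)) {
    out <- unclass(img)[, , keep, drop = FALSE]
    attr(out, "space") <- space
    out
  } else {
    img[, keep, drop = FALSE]
  }
}

#' Convert a linear RGB image to an analysis space
#'
#' One-stop conversion used by the pair-building and reporting stages.
#' For MB-DKL the adapting background defaults to the monitor mid-gray
#' (RGB 0.5) unless `background` is given.
#'
#' @param img a [color_image()] in linear RGB.
#' @param to target space: `"linearRGB"`, `"XYZ"`, `"LMS"`, `"MBDKL"`, `"LAB"`.
#' @param cal a [monitor_calibration()].
#' @param fundamentals cone fundamentals for LMS-based targets.
#' @param background LMS triplet for MB-DKL (default: monitor mid-gray).
#' @return A [color_image()] in the requested space.
#' @export
convert_space <- function(img, to, cal = default_monitor(),
                          fundamentals = cone_fundamentals(cal$grid),
                          background = NULL) {
  stopifnot(image_space(img) == "linearRGB")
  switch(to,
    linearRGB = img,
    XYZ = rgb_to_xyz(img, cal),
    LMS = rgb_to_lms(img, cal, fundamentals),
    LAB = {
      white <- as.numeric(calibration_to_matrix(cal) %*% rep(1, 3))
      xyz_to_lab(rgb_to_xyz(img, cal), white)
    },
    MBDKL = {
      lms <- rgb_to_lms(img, cal, fundamentals)
      if (is.null(background)) {
        m <- calibration_to_lms_matrix(cal, fundamentals)
        background <- as.numeric(m %*% rep(0.5, 3))
      }
      lms_to_mbdkl(lms, background)
    },
    stop("unknown target space: ", to))
}

#' Luminance image
#'
#' For linear RGB the luminance is the CIE Y channel from the calibration
#' matrix; for LMS it is L + M + S; XYZ uses Y; LAB uses L*.
#'
#' @param img a [color_image()].
#' @param cal calibration (needed for linear RGB input).
#' @return H x W numeric matrix.
#' @export
luminance_map <- function(img, cal = default_monitor()) {
  d <- dim(img)
  p <- pixel_matrix(img)
  y <- switch(image_space(img),
              linearRGB = as.numeric(p %*% calibration_to_matrix(cal)[2, ]),
              XYZ = p[, 2],
              LMS = rowSums(p),
              LAB = p[, 1],
              stop("no luminance convention for space ", image_space(img)))
  matrix(y, d[1], d[2])
}
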