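#' Spectral distributions on an explicit wavelength grid
#'
#' A `spectrum` is the package's container for any wavelength-sampled
#' quantity: illuminant power distributions, filter transmissions, surface
#' reflectances and sensor sensitivity curves.  Values live on a strictly
#' increasing wavelength grid in nanometres; resampling is linear with
#' zero-fill outside the tabulated support (mirroring how spectral renderers
#' typically ingest user data).
#'
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths (nm).
#' @param values numeric vector of the same length; must be finite.
#' @param bounded if `TRUE`, require values in `[0, 1]` (transmissions,
#'   reflectances).
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(wavelengths_nm, values, bounded = FALSE) {
  wavelengths_nm <- as.numeric(wavelengths_nm)
  values <- as.numeric(values)
  if (length(wavelengths_nm) != length(values)) {
    stop("wavelengths and values must have the same length")
  }
  if (length(wavelengths_nm) < 2L) stop("a spectrum needs at least 2 samples")
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing")
  }
  if (!all(is.finite(values))) stop("spectrum values must be finite")
  if (bounded && (any(values < 0) || any(values > 1))) {
    stop("bounded spectrum values must lie in [0, 1]")
  }
  structure(list(wavelengths_nm = wavelengths_nm, values = values),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum: %d samples, %.0f-%.0f nm, range [%.4g, %.4g]>\n",
              length(x$values), min(x$wavelengths_nm), max(x$wavelengths_nm),
              min(x$values), max(x$values)))
  invisible(x)
}

is_spectrum <- function(x) inherits(x, "spectrum")

#' Default wavelength grid
#'
#' 47 equally spaced bands over 360-830 nm, the sampling used by the
#' package's spectral engine.
#' @export
default_wavelength_grid <- function() seq(360, 830, length.out = 47)

#' Resample a spectrum onto a wavelength grid
#'
#' Linear interpolation; zero outside the tabulated support.
#'
#' @param spec a [spectrum()].
#' @param grid numeric vector of target wavelengths (nm).
#' @return Numeric vector of values on `grid`.
#' @export
resample_spectrum <- function(spec, grid) {
  stopifnot(is_spectrum(spec))
  stats::approx(spec$wavelengths_nm, spec$values, xout = grid,
                method = "linear", yleft = 0, yright = 0)$y
}

#' Integrate a spectrum against sensor sensitivities
#'
#' Computes the tristimulus response `sum(spd * sensor_i * dLambda)` for each
#' of three sensor curves, after resampling everything onto a common grid.
#'
#' @param spd a [spectrum()] (radiance / power distribution).
#' @param sensors list of 3 [spectrum()] objects (e.g. cone fundamentals or
#'   colour-matching functions).
#' @param grid common wavelength grid; defaults to [default_wavelength_grid()].
#' @return Numeric triplet.
#' @export
spectrum_to_tristimulus <- function(spd, sensors, grid = default_wavelength_grid()) {
  stopifnot(is_spectrum(spd), length(sensors) == 3L)
  sv <- resample_spectrum(spd, grid)
  smat <- vapply(sensors, resample_spectrum, numeric(length(grid)), grid = grid)
  if (all(sv == 0) || all(smat == 0)) {
    if (max(spd$wavelengths_nm) < min(grid) || min(spd$wavelengths_nm) > max(grid)) {
      stop("spectrum support does not overlap the integration grid")
    }
  }
  dl <- mean(diff(grid))
  as.numeric(crossprod(smat, sv)) * dl
}

# ---- bundled analytic sensitivity curves -----------------------------------
# Smooth analytic stand-ins for the measured curves; adequate for simulation
# and fully replaceable by user-supplied tabulated spectra.

# piecewise (two-sided) Gaussian used by the CIE 1931 analytic approximation
.pwgauss <- function(x, mu, s1, s2) {
  s <- ifelse(x < mu, s1, s2)
  exp(-0.5 * ((x - mu) / s)^2)
}

#' CIE 1931 colour-matching functions (analytic approximation)
#'
#' Multi-lobe Gaussian fit to the 2-degree standard observer.  Good to a few
#' percent, which is sufficient for the synthetic-scene engine; replace with
#' tabulated curves via [read_spectrum_csv()] when exact colorimetry against
#' measured data is required.
#'
#' @param grid wavelength grid (nm).
#' @return List of 3 [spectrum()] objects: xbar, ybar, zbar.
#' @export
cie1931_cmf <- function(grid = default_wavelength_grid()) {
  xb <- 1.056 * .pwgauss(grid, 599.8, 37.9, 31.0) +
        0.362 * .pwgauss(grid, 442.0, 16.0, 26.7) -
        0.065 * .pwgauss(grid, 501.1, 20.4, 26.2)
  yb <- 0.821 * .pwgauss(grid, 568.8, 46.9, 40.5) +
        0.286 * .pwgauss(grid, 530.9, 16.3, 31.1)
  zb <- 1.217 * .pwgauss(grid, 437.0, 11.8, 36.0) +
        0.681 * .pwgauss(grid, 459.0, 26.0, 13.8)
  list(xbar = spectrum(grid, pmax(xb, 0)),
       ybar = spectrum(grid, pmax(yb, 0)),
       zbar = spectrum(grid, pmax(zb, 0)))
}

#' Cone fundamentals (smooth synthetic stand-ins)
#'
#' Two-sided Gaussian approximations to the L, M and S cone spectral
#' sensitivities, peaking near 566, 541 and 441 nm.  With
#' `normalize = "equal_energy"` (the default) each curve is scaled so that an
#' equal-energy stimulus of unit intensity produces a response of exactly 1
#' in every cone class; `normalize = "none"` returns the raw curves.
#'
#' @param grid wavelength grid (nm).
#' @param normalize `"equal_energy"` or `"none"`.
#' @return List of 3 [spectrum()] objects: L, M, S.
#' @export
cone_fundamentals <- function(grid = default_wavelength_grid(),
                              normalize = c("equal_energy", "none")) {
  normalize <- match.arg(normalize)
  L <- .pwgauss(grid, 566, 55, 62)
  M <- .pwgauss(grid, 541, 48, 55)
  S <- .pwgauss(grid, 441, 26, 36)
  out <- list(L = L, M = M, S = S)
  dl <- mean(diff(grid))
  if (normalize == "equal_energy") {
    out <- lapply(out, function(v) v / (sum(v) * dl))
  }
  lapply(out, function(v) spectrum(grid, v))
}

#' Read / write two-column spectrum CSV files
#'
#' The on-disk interchange format is a two-column CSV
#' (`wavelength_nm`, `value`); a header row is optional.
#'
#' @param path file path.
#' @return [read_spectrum_csv()] returns a [spectrum()].
#' @export
read_spectrum_csv <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", first)
  d <- utils::read.csv(path, header = has_header)
  spectrum(d[[1L]], d[[2L]])
}

#' @rdname read_spectrum_csv
#' @param spec a [spectrum()] to write.
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(is_spectrum(spec))
  utils::write.csv(
    data.frame(wavelength_nm = spec$wavelengths_nm, value = spec$values),
    path, row.names = FALSE)
  invisible(path)
}
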