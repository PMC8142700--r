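#' Monitor calibration
#'
#' Describes a three-primary display either by the CIE 1931 xyY coordinates
#' of its primaries at maximum drive, by the primaries' emission spectra, or
#' both.  The reference white is the sum of the three primaries at maximum.
#' An optional decoding gamma (default 2.2) is applied when 8/16-bit images
#' are loaded; float images are assumed already linear.
#'
#' @param primaries data.frame with columns `x`, `y`, `Y` and one row per
#'   primary (R, G, B order), or `NULL` if spectra are given.
#' @param primary_spectra list of 3 [spectrum()] emission spectra at maximum
#'   drive (R, G, B order), or `NULL`.
#' @param gamma decoding gamma for integer-coded images.
#' @param grid wavelength grid used when deriving xyY from spectra.
#' @param validate reject degenerate primaries (singular RGB->XYZ matrix)?
#'   Disable only for deliberately degenerate configurations.
#' @return Object of class `monitor_calibration`.
#' @export
monitor_calibration <- function(primaries = NULL, primary_spectra = NULL,
                                gamma = 2.2, grid = default_wavelength_grid(),
                                validate = TRUE) {
  if (is.null(primaries) && is.null(primary_spectra)) {
    stop("supply primary xyY coordinates and/or emission spectra")
  }
  if (!is.null(primary_spectra)) {
    stopifnot(length(primary_spectra) == 3L,
              all(vapply(primary_spectra, is_spectrum, logical(1))))
    if (is.null(primaries)) {
      cmf <- cie1931_cmf(grid)
      xyz <- t(vapply(primary_spectra, spectrum_to_tristimulus, numeric(3),
                      sensors = cmf, grid = grid))
      s <- rowSums(xyz)
      primaries <- data.frame(x = xyz[, 1] / s, y = xyz[, 2] / s, Y = xyz[, 2])
    }
  }
  stopifnot(is.data.frame(primaries), nrow(primaries) == 3L,
            all(c("x", "y", "Y") %in% names(primaries)))
  if (any(primaries$y <= 0)) stop("invalid calibration: primary y must be > 0")
  cal <- structure(list(primaries = primaries, primary_spectra = primary_spectra,
                        gamma = gamma, grid = grid),
                   class = "monitor_calibration")
  m <- calibration_to_matrix(cal)
  if (validate) {
    if (abs(det(m)) < 1e-12 * max(abs(m))^3) {
      stop("degenerate primaries: RGB->XYZ matrix is singular")
    }
    if (any(m %*% rep(1, 3) <= 0)) stop("derived white point must be all-positive")
  }
  cal
}

#' @export
print.monitor_calibration <- function(x, ...) {
  w <- calibration_to_matrix(x) %*% rep(1, 3)
  cat(sprintf("<monitor_calibration: white XYZ = (%.4g, %.4g, %.4g), gamma %.2f%s>\n",
              w[1], w[2], w[3], x$gamma,
              if (is.null(x$primary_spectra)) "" else ", with primary spectra"))
  invisible(x)
}

#' Linear-RGB to XYZ matrix from a calibration
#'
#' Column i holds the XYZ tristimulus of primary i at maximum drive,
#' reconstructed from its chromaticity and luminance as
#' `X = x*Y/y`, `Y = Y`, `Z = (1 - x - y)*Y/y`.  By construction
#' `matrix %*% c(1,1,1)` is the reference white.
#'
#' @param cal a [monitor_calibration()].
#' @return 3x3 numeric matrix mapping linear RGB column vectors to XYZ.
#' @export
calibration_to_matrix <- function(cal) {
  stopifnot(inherits(cal, "monitor_calibration"))
  p <- cal$primaries
  if (any(p$y <= 0)) stop("invalid calibration: primary y must be > 0")
  m <- rbind(X = p$x * p$Y / p$y,
             Y = p$Y,
             Z = (1 - p$x - p$y) * p$Y / p$y)
  colnames(m) <- c("R", "G", "B")
  m
}

#' Per-primary maximum LMS excitation matrix
#'
#' Column i holds the LMS excitation produced by primary i at maximum drive,
#' computed from the calibration's emission spectra and the supplied cone
#' fundamentals.  Required by [rgb_to_lms()].
#'
#' @param cal a [monitor_calibration()] that carries primary spectra.
#' @param fundamentals list of 3 sensitivity [spectrum()]s
#'   (default: equal-energy-normalized [cone_fundamentals()]).
#' @return 3x3 matrix (rows L, M, S; columns R, G, B).
#' @export
calibration_to_lms_matrix <- function(cal, fundamentals = cone_fundamentals(cal$grid)) {
  stopifnot(inherits(cal, "monitor_calibration"))
  if (is.null(cal$primary_spectra)) {
    stop("configuration error: calibration has no primary spectra; ",
         "supply them (or a precomputed LMS matrix) to compute cone excitations")
  }
  m <- vapply(cal$primary_spectra, spectrum_to_tristimulus, numeric(3),
              sensors = fundamentals, grid = cal$grid)
  dimnames(m) <- list(c("L", "M", "S"), c("R", "G", "B"))
  m
}

#' Bundled example calibrations
#'
#' `eizo_calibration()` carries the xyY phosphor coordinates of a calibrated
#' 10-bit EIZO ColorEdge CG245W (red x 0.6733, y 0.3088, Y 37.223 cd/m2;
#' green x 0.2103, y 0.6869, Y 86.659; blue x 0.1564, y 0.0554, Y 7.9206).
#' It has no primary spectra, so it supports XYZ/CIELAB but not LMS.
#'
#' `default_monitor()` is a synthetic monitor model whose primaries have
#' smooth Gaussian emission spectra (peaks 610, 545, 465 nm); it supports
#' every conversion in the package and is the default throughout the
#' synthetic-scene pipeline.
#'
#' @return A [monitor_calibration()].
#' @export
eizo_calibration <- function() {
  monitor_calibration(primaries = data.frame(
    x = c(0.6733, 0.2103, 0.1564),
    y = c(0.3088, 0.6869, 0.0554),
    Y = c(37.223, 86.659, 7.9206)))
}

#' @rdname eizo_calibration
#' @export
default_monitor <- function() {
  grid <- default_wavelength_grid()
  mk <- function(mu, sd, amp) spectrum(grid, amp * exp(-0.5 * ((grid - mu) / sd)^2))
  monitor_calibration(primary_spectra = list(R = mk(610, 22, 1.00),
                                             G = mk(545, 28, 0.85),
                                             B = mk(465, 20, 0.90)),
                      grid = grid)
}

#' Read a calibration from JSON
#'
#' Accepts either `{"primaries": [{"x":..,"y":..,"Y":..} x3], "gamma": ..}`
#' or `{"primary_spectra": ["r.csv","g.csv","b.csv"], "gamma": ..}` with
#' paths resolved relative to the JSON file.
#'
#' @param path JSON file path.
#' @return A [monitor_calibration()].
#' @export
read_calibration_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gamma <- if (is.null(j$gamma)) 2.2 else j$gamma
  if (!is.null(j$primaries)) {
    monitor_calibration(primaries = as.data.frame(j$primaries), gamma = gamma)
  } else if (!is.null(j$primary_spectra)) {
    paths <- file.path(dirname(path), j$primary_spectra)
    monitor_calibration(primary_spectra = lapply(paths, read_spectrum_csv),
                        gamma = gamma)
  } else {
    stop("calibration JSON needs 'primaries' or 'primary_spectra'")
  }
}
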