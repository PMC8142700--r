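#' Colour images and region masks
#'
#' A `color_image` is an H x W x 3 numeric array tagged with the colour space
#' its values live in (`"linearRGB"`, `"XYZ"`, `"LMS"`, `"MBDKL"` or
#' `"LAB"`).  Linear RGB nominally spans `[0, 1]`; values above 1 are legal
#' (HDR) and flagged via the `"hdr"` attribute.  A `region_mask` is an H x W
#' logical matrix with a semantic label.
#'
#' @param data H x W x 3 numeric array of finite values.
#' @param space one of the five recognized space tags.
#' @return `color_image()` returns an object of class `color_image`.
#' @export
color_image <- function(data, space = c("linearRGB", "XYZ", "LMS", "MBDKL", "LAB")) {
  space <- match.arg(space)
  stopifnot(is.array(data), length(dim(data)) == 3L, dim(data)[3] == 3L,
            dim(data)[1] >= 1L, dim(data)[2] >= 1L)
  if (!all(is.finite(data))) stop("color_image entries must be finite")
  structure(data, space = space, hdr = (space == "linearRGB" && any(data > 1)),
            class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<color_image %dx%d in %s%s>\n", d[1], d[2], attr(x, "space"),
              if (isTRUE(attr(x, "hdr"))) " (HDR)" else ""))
  invisible(x)
}

image_space <- function(img) attr(img, "space")

#' @rdname color_image
#' @param mask H x W logical matrix.
#' @param label semantic label for the mask.
#' @export
region_mask <- function(mask, label = c("custom", "object", "highlight",
                                        "caustic", "shadow", "dark")) {
  label <- match.arg(label)
  stopifnot(is.matrix(mask), is.logical(mask))
  structure(mask, label = label, class = c("region_mask", "matrix", "array"))
}

as_mask <- function(m, label = "custom") {
  if (inherits(m, "region_mask")) m else region_mask(m, label)
}

check_mask_for <- function(mask, img, require_nonempty = TRUE) {
  d <- dim(img)
  if (!all(dim(mask)[1:2] == d[1:2])) stop("mask dimensions do not match image")
  if (require_nonempty && !any(mask)) stop("mask selects no pixels")
  invisible(TRUE)
}

#' Extract masked pixels as an N x 3 matrix
#'
#' Pixels are returned in column-major scan order, matching `which(mask)`.
#'
#' @param img a [color_image()].
#' @param mask optional logical H x W matrix; `NULL` takes every pixel.
#' @return N x 3 numeric matrix.
#' @export
pixel_matrix <- function(img, mask = NULL) {
  d <- dim(img)
  m <- matrix(as.numeric(img), d[1] * d[2], 3L)
  if (is.null(mask)) return(m)
  check_mask_for(mask, img)
  m[as.vector(mask), , drop = FALSE]
}

# rebuild an image from a full-pixel matrix
matrix_to_image <- function(m, dim2, space) {
  color_image(array(m, c(dim2[1], dim2[2], 3L)), space = space)
}

# ---- file I/O ---------------------------------------------------------------

#' Read and write images
#'
#' PNG files (8/16-bit) are decoded to linear RGB using the calibration's
#' decoding gamma; float text images (see [write_color_image_txt()]) are
#' taken as already linear.  Masks are single-channel PNGs where any nonzero
#' sample is `TRUE`.
#'
#' @param path file path.
#' @param cal calibration supplying the decoding gamma.
#' @return A [color_image()] in linear RGB.
#' @export
read_image_png <- function(path, cal = default_monitor()) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  a <- a[, , 1:3, drop = FALSE]
  color_image(a^cal$gamma, space = "linearRGB")
}

#' @rdname read_image_png
#' @param img a linear RGB [color_image()] to encode.
#' @export
write_image_png <- function(img, path, cal = default_monitor()) {
  stopifnot(image_space(img) == "linearRGB")
  a <- pmin(pmax(unclass(img), 0), 1)^(1 / cal$gamma)
  attributes(a) <- list(dim = dim(img))
  png::writePNG(a, path)
  invisible(path)
}

#' @rdname read_image_png
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  region_mask(a > 0)
}

#' @rdname read_image_png
#' @param mask a logical mask to write.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Lossless text round-trip for float images
#'
#' Plain-text storage for linear float images: a header line
#' `H W <space>` followed by one `R G B` row per pixel in column-major
#' order, printed at full double precision.
#'
#' @param img a [color_image()].
#' @param path file path.
#' @export
write_color_image_txt <- function(img, path) {
  con <- file(path, "w")
  on.exit(close(con))
  d <- dim(img)
  writeLines(sprintf("%d %d %s", d[1], d[2], image_space(img)), con)
  m <- pixel_matrix(img)
  writeLines(apply(format(m, digits = 17, scientific = TRUE, trim = TRUE),
                   1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_color_image_txt
#' @export
read_color_image_txt <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), " ")[[1L]]
  h <- as.integer(hdr[1]); w <- as.integer(hdr[2])
  m <- as.matrix(utils::read.table(path, skip = 1L))
  matrix_to_image(m, c(h, w), hdr[3])
}
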