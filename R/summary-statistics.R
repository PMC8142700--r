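#' Per-object colour summaries
#'
#' Candidate predictors of the colour a viewer assigns to an object, all
#' computed on the CIELAB colour distribution of the masked region:
#'
#' * `mean_lab_color()` — component-wise mean in LAB (explicitly the mean of
#'   the LAB distribution, not the colorimetric mean of linear RGB);
#' * `white_point()` — mean colour of the brightest few percent of pixels
#'   (by L*), specular highlights excluded;
#' * `most_saturated()` — mean colour of the top few percent of pixels by
#'   the saturation score `sqrt(a*^2 + b*^2) / L*`, after excluding
#'   highlights and pixels with extreme lightness;
#' * `most_frequent()` — centre of the most populated unit cube of an
#'   axis-aligned partition of the LAB cloud's bounding box.
#'
#' Fractional selections take `ceiling(fraction * N)` pixels (at least 1).
#'
#' @param img a [color_image()] in LAB.
#' @param mask logical region mask (non-empty).
#' @return A `summary_color`: LAB triplet with attributes `statistic` and
#'   `n_pixels_used`.
#' @export
mean_lab_color <- function(img, mask) {
  stopifnot(image_space(img) == "LAB")
  check_mask_for(mask, img)
  p <- pixel_matrix(img, mask)
  new_summary_color(colMeans(p), "mean", nrow(p))
}

new_summary_color <- function(lab, tag, n) {
  names(lab) <- c("L", "a", "b")
  structure(lab, statistic = tag, n_pixels_used = as.integer(n),
            class = "summary_color")
}

#' @export
print.summary_color <- function(x, ...) {
  cat(sprintf("<summary_color %s: L* %.3f, a* %.3f, b* %.3f (n = %d)>\n",
              attr(x, "statistic"), x[1], x[2], x[3], attr(x, "n_pixels_used")))
  invisible(x)
}

top_fraction_count <- function(n, fraction) max(1L, as.integer(ceiling(fraction * n)))

#' @rdname mean_lab_color
#' @param highlights logical highlight mask to exclude (may be `NULL`).
#' @param top_fraction fraction of pixels selected (default 0.05).
#' @export
white_point <- function(img, mask, highlights = NULL, top_fraction = 0.05) {
  stopifnot(image_space(img) == "LAB")
  check_mask_for(mask, img)
  if (is.null(highlights)) highlights <- matrix(FALSE, nrow(mask), ncol(mask))
  eff <- mask & !highlights
  if (!any(eff)) stop("no pixels left after highlight exclusion")
  p <- pixel_matrix(img, eff)
  k <- top_fraction_count(nrow(p), top_fraction)
  sel <- order(-p[, 1])[seq_len(k)]  # brightest ranked by L*, stable order
  new_summary_color(colMeans(p[sel, , drop = FALSE]), "white_point", k)
}

#' @rdname mean_lab_color
#' @param L_min,L_max lightness window; pixels with `L* < L_min` (guards the
#'   division by lightness) or `L* > L_max` (guards residual bright specular
#'   pixels) are excluded.
#' @export
most_saturated <- function(img, mask, highlights = NULL, L_min = 1, L_max = 85,
                           top_fraction = 0.05) {
  stopifnot(image_space(img) == "LAB")
  check_mask_for(mask, img)
  if (is.null(highlights)) highlights <- matrix(FALSE, nrow(mask), ncol(mask))
  eff <- mask & !highlights
  p <- pixel_matrix(img, eff)
  keep <- p[, 1] >= L_min & p[, 1] <= L_max
  if (!any(keep)) {
    stop(sprintf(paste0("no pixels survive the filters: %d in mask, %d after ",
                        "highlight exclusion, 0 inside the L* window [%g, %g]"),
                 sum(mask), nrow(p), L_min, L_max))
  }
  p <- p[keep, , drop = FALSE]
  s <- sqrt(p[, 2]^2 + p[, 3]^2) / p[, 1]
  k <- top_fraction_count(nrow(p), top_fraction)
  sel <- order(-s)[seq_len(k)]
  new_summary_color(colMeans(p[sel, , drop = FALSE]), "most_saturated", k)
}

#' @rdname mean_lab_color
#' @param box_size side length of the partition cubes in LAB units
#'   (default 1).
#' @details `most_frequent()` partitions the bounding box starting at its
#' minimum corner; a final partial cube is included when the extent is not a
#' multiple of `box_size`.  Equal counts are broken toward the cube with the
#' lexicographically lowest (L*, a*, b*) origin.
#' @export
most_frequent <- function(img, mask, highlights = NULL, box_size = 1.0) {
  stopifnot(image_space(img) == "LAB", box_size > 0)
  check_mask_for(mask, img)
  if (is.null(highlights)) highlights <- matrix(FALSE, nrow(mask), ncol(mask))
  eff <- mask & !highlights
  if (!any(eff)) stop("no pixels left after highlight exclusion")
  p <- pixel_matrix(img, eff)
  lo <- apply(p, 2L, min)
  idx <- floor(sweep(p, 2L, lo) / box_size)
  # points exactly on the far face fall into the last (possibly partial) cube
  nmax <- pmax(ceiling((apply(p, 2L, max) - lo) / box_size) - 1, 0)
  idx <- pmin(idx, matrix(nmax, nrow(idx), 3L, byrow = TRUE))
  key <- paste(idx[, 1], idx[, 2], idx[, 3])
  counts <- table(key)
  winners <- names(counts)[counts == max(counts)]
  wi <- do.call(rbind, lapply(strsplit(winners, " "), as.numeric))
  ord <- order(wi[, 1], wi[, 2], wi[, 3])
  w <- wi[ord[1L], ]
  center <- lo + (w + 0.5) * box_size
  new_summary_color(center, "most_frequent", max(counts))
}

#' CIEDE2000 threshold map
#'
#' Builds a companion image that is black outside the mask; masked pixels
#' whose CIELAB colour lies within `threshold` CIEDE2000 units of the
#' reference keep their original RGB, and all other masked pixels are
#' replaced by a dimmed grayscale
#' `(0.299 R + 0.587 G + 0.114 B) / dim` so residual specular brightness
#' does not read as colour.
#'
#' @param img a [color_image()] in linear RGB.
#' @param mask logical region mask.
#' @param reference LAB triplet the map is thresholded against.
#' @param threshold CIEDE2000 threshold in JND units (default 15).
#' @param dim grayscale dimming divisor (default 1.5).
#' @param cal calibration for the RGB -> LAB conversion.
#' @return A `diff_map`: linear RGB [color_image()] with attributes
#'   `threshold`, `reference` and `within` (the logical pass mask).
#' @export
ciede_map <- function(img, mask, reference, threshold = 15, dim = 1.5,
                      cal = default_monitor()) {
  stopifnot(image_space(img) == "linearRGB", threshold > 0, length(reference) == 3L)
  check_mask_for(mask, img, require_nonempty = FALSE)
  lab <- convert_space(img, "LAB", cal)
  d <- ciede2000(pixel_matrix(lab), as.numeric(reference))
  h <- nrow(mask); w <- ncol(mask)
  pass <- matrix(d <= threshold, h, w) & mask
  rgbm <- pixel_matrix(img)
  out <- matrix(0, h * w, 3L)
  pv <- as.vector(pass)
  out[pv, ] <- rgbm[pv, , drop = FALSE]
  grayv <- as.vector(mask & !pass)
  gray <- (0.299 * rgbm[grayv, 1] + 0.587 * rgbm[grayv, 2] + 0.114 * rgbm[grayv, 3]) / dim
  out[grayv, ] <- gray
  res <- matrix_to_image(out, c(h, w), "linearRGB")
  attr(res, "threshold") <- threshold
  attr(res, "reference") <- as.numeric(reference)
  attr(res, "within") <- pass
  class(res) <- c("diff_map", class(res))
  res
}
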