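#' Colour vector field between an unfiltered and a filtered image
#'
#' Each masked pixel contributes one vector whose tail is the pixel's colour
#' before filtering and whose tip is its colour after filtering.  Many
#' pixels may share a tail (broad uniform regions spread out after
#' filtering), so the raw field is a one-to-many sample set.
#'
#' @param unfiltered,filtered [color_image()]s in linear RGB, same size.
#' @param mask logical mask of filtered pixels.
#' @param space analysis space for the colours.
#' @param cal,fundamentals colorimetry configuration.
#' @return A `vector_field_samples`: list with `tails`, `tips` (N x D) and
#'   `space`.
#' @export
build_field <- function(unfiltered, filtered, mask, space = "MBDKL",
                        cal = default_monitor(),
                        fundamentals = cone_fundamentals(cal$grid)) {
  pairs <- build_pairs(unfiltered, filtered, mask, space = space,
                       cal = cal, fundamentals = fundamentals)
  field_samples(pairs$a, pairs$b, space)
}

#' @rdname build_field
#' @param tails,tips N x D matrices (D = 2 or 3).
#' @export
field_samples <- function(tails, tips, space = "custom") {
  tails <- as.matrix(tails); tips <- as.matrix(tips)
  stopifnot(nrow(tails) == nrow(tips), ncol(tails) == ncol(tips),
            ncol(tails) %in% 2:3, all(is.finite(tails)), all(is.finite(tips)))
  structure(list(tails = tails, tips = tips, space = space),
            class = "vector_field_samples")
}

#' @export
print.vector_field_samples <- function(x, ...) {
  cat(sprintf("<vector_field_samples: %d vectors, D = %d, space %s>\n",
              nrow(x$tails), ncol(x$tails), x$space))
  invisible(x)
}

#' Project vector-field samples onto a coordinate plane
#'
#' @param samples a `vector_field_samples`.
#' @param axes which two axes to keep, e.g. `c(1, 2)` for the
#'   red-green/blue-yellow plane of MB-DKL or `c(2, 3)` for
#'   blue-yellow/light-dark.
#' @return A 2-D `vector_field_samples`.
#' @export
project_field <- function(samples, axes = c(1L, 2L)) {
  stopifnot(length(axes) == 2L)
  field_samples(samples$tails[, axes, drop = FALSE],
                samples$tips[, axes, drop = FALSE],
                paste0(samples$space, "[", paste(axes, collapse = ","), "]"))
}

#' Interpolate a sampled vector field onto a regular grid
#'
#' The bounding box spans the union of all tails and tips.  At each of
#' `n_per_axis` equally spaced grid points per axis, the vectors whose
#' binning key (tail position by default) falls inside an axis-aligned
#' averaging box centred on the grid point — side length equal to the grid
#' step — are averaged component-wise; grid points whose box is empty store
#' the zero vector.  A degenerate axis (zero extent) is padded by a
#' machine-scale epsilon with a warning.
#'
#' @param samples a `vector_field_samples`.
#' @param n_per_axis grid resolution per axis (default 100).
#' @param bin_on `"tail"` (default; the field is indexed by the pre-filter
#'   colour), `"tip"` or `"midpoint"`.
#' @return A `grid_field`: list with `box_min`, `box_max`, `n_per_axis`,
#'   `step`, `vectors` (array n^D x D flattened as a matrix plus dim info)
#'   and `counts`.
#' @export
interpolate_field <- function(samples, n_per_axis = 100L,
                              bin_on = c("tail", "tip", "midpoint")) {
  bin_on <- match.arg(bin_on)
  stopifnot(n_per_axis >= 2L, nrow(samples$tails) >= 1L)
  D <- ncol(samples$tails)
  all_pts <- rbind(samples$tails, samples$tips)
  box_min <- apply(all_pts, 2L, min)
  box_max <- apply(all_pts, 2L, max)
  degen <- box_max - box_min <= 0
  if (any(degen)) {
    eps <- pmax(abs(box_min), 1) * .Machine$double.eps^0.5
    box_min[degen] <- box_min[degen] - eps[degen]
    box_max[degen] <- box_max[degen] + eps[degen]
    warning("degenerate bounding-box axis padded by machine epsilon")
  }
  step <- (box_max - box_min) / (n_per_axis - 1L)
  key <- switch(bin_on,
                tail = samples$tails,
                tip = samples$tips,
                midpoint = (samples$tails + samples$tips) / 2)
  vec <- samples$tips - samples$tails
  # nearest grid point == centred averaging box of side `step`
  idx <- round(sweep(sweep(key, 2L, box_min), 2L, step, "/")) + 1L
  idx <- pmin(pmax(idx, 1L), n_per_axis)
  lin <- idx[, 1L]
  mult <- 1L
  for (d in seq_len(D - 1L)) {
    mult <- mult * n_per_axis
    lin <- lin + (idx[, d + 1L] - 1L) * mult
  }
  ncell <- n_per_axis^D
  counts <- tabulate(lin, nbins = ncell)
  vectors <- matrix(0, ncell, D)
  sums <- rowsum(vec, lin)
  occ <- as.integer(rownames(sums))
  vectors[occ, ] <- sums / counts[occ]
  structure(list(box_min = box_min, box_max = box_max,
                 n_per_axis = as.integer(n_per_axis), step = step,
                 vectors = vectors, counts = counts, dims = D,
                 space = samples$space, bin_on = bin_on),
            class = "grid_field")
}

#' @export
print.grid_field <- function(x, ...) {
  cat(sprintf("<grid_field: %d^%d grid, %d occupied cells, space %s>\n",
              x$n_per_axis, x$dims, sum(x$counts > 0), x$space))
  invisible(x)
}

# linear cell index from integer axis indices
grid_cell_index <- function(field, idx) {
  n <- field$n_per_axis
  lin <- idx[1L]
  mult <- 1
  for (d in seq_len(field$dims - 1L)) {
    mult <- mult * n
    lin <- lin + (idx[d + 1L] - 1L) * mult
  }
  lin
}

# bilinear interpolation of a 2-D grid_field at point p; zero outside box
field_at <- function(field, p) {
  stopifnot(field$dims == 2L)
  g <- (p - field$box_min) / field$step
  i0 <- floor(g)
  f <- g - i0
  i0 <- i0 + 1
  v <- c(0, 0)
  for (dx in 0:1) for (dy in 0:1) {
    ix <- i0[1L] + dx; iy <- i0[2L] + dy
    if (ix < 1 || ix > field$n_per_axis || iy < 1 || iy > field$n_per_axis) next
    wgt <- (if (dx == 0) 1 - f[1L] else f[1L]) * (if (dy == 0) 1 - f[2L] else f[2L])
    v <- v + wgt * field$vectors[grid_cell_index(field, c(ix, iy)), ]
  }
  v
}

#' Trace streamlines through a 2-D grid field
#'
#' Classical fourth-order Runge-Kutta integration of the interpolated field
#' (bilinear within cells), emulating streamline/streamslice analyses of
#' colour convergence.  A streamline terminates when it leaves the bounding
#' box (`left_box`), when the local speed drops below `stagnation_tol`
#' (`stagnation`) — for a converging field this is the arrival at the sink —
#' or at `max_steps`.
#'
#' @param field a 2-D `grid_field` (use [project_field()] +
#'   [interpolate_field()] for 3-D data).
#' @param seeds N x 2 matrix of seed points; default is an 8 x 8 lattice
#'   spanning the interior of the box.
#' @param step integration step in field-time units; default makes the first
#'   displacement about half a grid cell at the maximum field speed.
#' @param max_steps cap on integration steps per streamline.
#' @param stagnation_tol speed below which integration stops; default
#'   `1e-6 * max speed` in the field.
#' @return List of `streamline` objects: each a list with `points` (M x 2)
#'   and `termination`.
#' @export
trace_streamlines <- function(field, seeds = NULL, step = NULL,
                              max_steps = 2000L, stagnation_tol = NULL) {
  stopifnot(inherits(field, "grid_field"), field$dims == 2L)
  if (is.null(seeds)) {
    sx <- seq(field$box_min[1L], field$box_max[1L], length.out = 10L)[2:9]
    sy <- seq(field$box_min[2L], field$box_max[2L], length.out = 10L)[2:9]
    seeds <- as.matrix(expand.grid(sx, sy))
  }
  seeds <- matrix(seeds, ncol = 2L)
  vmax <- max(sqrt(rowSums(field$vectors^2)))
  if (vmax == 0) vmax <- 1
  if (is.null(step)) step <- 0.5 * min(field$step) / vmax
  if (is.null(stagnation_tol)) stagnation_tol <- 1e-6 * vmax
  inside <- function(p) all(p >= field$box_min) && all(p <= field$box_max)
  lapply(seq_len(nrow(seeds)), function(i) {
    p <- seeds[i, ]
    if (!inside(p)) {
      return(structure(list(points = matrix(p, 1L, 2L), termination = "left_box"),
                       class = "streamline"))
    }
    pts <- matrix(NA_real_, max_steps + 1L, 2L)
    pts[1L, ] <- p
    term <- "max_steps"
    nkept <- 1L
    for (s in seq_len(max_steps)) {
      v1 <- field_at(field, p)
      if (sqrt(sum(v1^2)) < stagnation_tol) { term <- "stagnation"; break }
      k1 <- v1
      k2 <- field_at(field, p + step / 2 * k1)
      k3 <- field_at(field, p + step / 2 * k2)
      k4 <- field_at(field, p + step * k3)
      pn <- p + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!inside(pn)) { term <- "left_box"; break }
      p <- pn
      nkept <- nkept + 1L
      pts[nkept, ] <- p
    }
    structure(list(points = pts[seq_len(nkept), , drop = FALSE],
                   termination = term),
              class = "streamline")
  })
}

#' Fixed point of a fitted affine map
#'
#' The convergence point the fitted map pushes colours toward: the solution
#' of `(I - M) p = t` (12-parameter family) or `p = t / (1 - beta)`
#' (4-parameter family; identical to the "over" operator's convergence
#' colour).  Returns `point = NULL` with `diverged = TRUE` when the system
#' is singular (`beta = 1`) or the map is non-contracting (spectral radius
#' at least 1), since iteration of such a map does not approach the point.
#'
#' @param fit an `affine_fit` of family `affine12`, `affine4` or `over`.
#' @param tol singularity tolerance.
#' @return List with `point` (D-vector or `NULL`), `diverged`,
#'   `spectral_radius`.
#' @export
affine_fixed_point <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "affine_fit"))
  D <- fit$dims
  if (!is.null(fit$M)) {
    rho <- max(Mod(eigen(fit$M, only.values = TRUE)$values))
    A <- diag(D) - fit$M
    if (abs(det(A)) < tol || rho >= 1) {
      return(list(point = NULL, diverged = TRUE, spectral_radius = rho))
    }
    list(point = as.numeric(solve(A, fit$t)), diverged = FALSE,
         spectral_radius = rho)
  } else {
    rho <- abs(fit$beta)
    if (abs(1 - fit$beta) < tol || rho >= 1) {
      return(list(point = NULL, diverged = TRUE, spectral_radius = rho))
    }
    list(point = as.numeric(fit$t / (1 - fit$beta)), diverged = FALSE,
         spectral_radius = rho)
  }
}

#' Model-free convergence point of a sampled vector field
#'
#' Least-squares point minimising the summed squared perpendicular distance
#' to the lines through each (tail, direction) sample — the geometric
#' "crossing point" of the field, independent of any affine model.
#' Zero-length vectors are dropped; the normal equations require at least
#' two non-parallel directions.
#'
#' @param samples a `vector_field_samples`.
#' @param min_length vectors shorter than this are ignored.
#' @return List with `point` (D-vector) and `residual` (mean perpendicular
#'   distance).
#' @export
field_convergence_point <- function(samples, min_length = 1e-12) {
  v <- samples$tips - samples$tails
  len <- sqrt(rowSums(v^2))
  keep <- len > min_length
  if (sum(keep) < 2L) stop("need at least 2 non-zero vectors")
  d <- v[keep, , drop = FALSE] / len[keep]
  tails <- samples$tails[keep, , drop = FALSE]
  D <- ncol(d)
  A <- matrix(0, D, D)
  rhs <- numeric(D)
  for (i in seq_len(nrow(d))) {
    P <- diag(D) - tcrossprod(d[i, ])
    A <- A + P
    rhs <- rhs + P %*% tails[i, ]
  }
  if (rcond(A) < 1e-12) stop("vectors are (nearly) all parallel; no unique crossing point")
  p <- as.numeric(solve(A, rhs))
  perp <- vapply(seq_len(nrow(d)), function(i) {
    r <- p - tails[i, ]
    sqrt(sum((r - sum(r * d[i, ]) * d[i, ])^2))
  }, numeric(1))
  list(point = p, residual = mean(perp))
}
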