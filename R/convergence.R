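#' Build unfiltered/filtered colour pairs
#'
#' Converts both images to the requested analysis space, optionally projects
#' into the isoluminant plane (dropping the luminance/lightness component),
#' and pairs colours pixel-by-pixel over the mask.  Exclusion masks
#' (highlights, all specular, dark pixels) are subtracted from the mask
#' before pairing.
#'
#' @param unfiltered,filtered [color_image()]s in linear RGB, same size.
#' @param mask logical object mask (same mask indexes both images).
#' @param space analysis space: `"LMS"`, `"MBDKL"`, `"LAB"` or `"linearRGB"`.
#' @param isoluminant drop the luminance component (MBDKL/LAB only)?
#' @param exclude list of logical masks of pixels to drop.
#' @param cal,fundamentals colorimetry configuration.
#' @return A `color_pair_set`: list with `a` (unfiltered colours), `b`
#'   (filtered colours), `space`, `dims`.
#' @export
build_pairs <- function(unfiltered, filtered, mask, space = "MBDKL",
                        isoluminant = FALSE, exclude = list(),
                        cal = default_monitor(),
                        fundamentals = cone_fundamentals(cal$grid)) {
  if (!all(dim(unfiltered) == dim(filtered))) stop("image sizes differ")
  check_mask_for(mask, unfiltered)
  eff <- mask
  for (ex in exclude) eff <- eff & !ex
  if (!any(eff)) stop("no pixels remain after exclusions")
  au <- convert_space(unfiltered, space, cal, fundamentals)
  bf <- convert_space(filtered, space, cal, fundamentals)
  a <- pixel_matrix(au, eff)
  b <- pixel_matrix(bf, eff)
  if (isoluminant) {
    a <- project_isoluminant(a, space)
    b <- project_isoluminant(b, space)
  }
  new_pairs(a, b, space)
}

#' @rdname build_pairs
#' @param a,b N x D matrices of unfiltered / filtered colours (same pixel
#'   order) for constructing a pair set directly.
#' @export
color_pairs <- function(a, b, space = "custom") {
  new_pairs(as.matrix(a), as.matrix(b), space)
}

new_pairs <- function(a, b, space) {
  stopifnot(nrow(a) == nrow(b), ncol(a) == ncol(b), ncol(a) %in% 2:3,
            all(is.finite(a)), all(is.finite(b)))
  structure(list(a = a, b = b, space = space, dims = ncol(a)),
            class = "color_pair_set")
}

#' @export
print.color_pair_set <- function(x, ...) {
  cat(sprintf("<color_pair_set: %d pairs, D = %d, space %s>\n",
              nrow(x$a), x$dims, x$space))
  invisible(x)
}

pair_rmse <- function(resid) sqrt(mean(rowSums(resid^2)))

#' Relative reduction in prediction error
#'
#' `(rmse_identity - rmse_model) / rmse_identity`: 1 for a perfect model,
#' 0 for one no better than leaving the colours untouched.  Undefined when
#' the identity baseline is already perfect.
#'
#' @param rmse_model,rmse_identity non-negative RMSE values.
#' @return Numeric scalar, at most 1.
#' @export
rrpe <- function(rmse_model, rmse_identity) {
  if (rmse_identity <= 0) {
    stop("degenerate baseline: identity RMSE is zero, RRPE undefined")
  }
  (rmse_identity - rmse_model) / rmse_identity
}

new_affine_fit <- function(family, pairs, M = NULL, beta = NULL, t,
                           c_conv = NULL, representable = TRUE) {
  pred <- if (!is.null(M)) pairs$a %*% t(M) else pairs$a * beta
  pred <- sweep(pred, 2L, t, "+")
  rm <- pair_rmse(pred - pairs$b)
  ri <- pair_rmse(pairs$a - pairs$b)
  structure(list(family = family, M = M, beta = beta, t = t, c_conv = c_conv,
                 representable = representable,
                 rmse_model = rm, rmse_identity = ri,
                 rrpe = rrpe(rm, ri), space = pairs$space, dims = pairs$dims,
                 n = nrow(pairs$a)),
            class = "affine_fit")
}

#' @export
print.affine_fit <- function(x, ...) {
  cat(sprintf("<affine_fit %s (%s, D=%d, n=%d): RMSE %.4g vs identity %.4g, RRPE %.4f>\n",
              x$family, x$space, x$dims, x$n, x$rmse_model, x$rmse_identity, x$rrpe))
  invisible(x)
}

#' Fit the affine convergence models
#'
#' `fit_affine12()` fits the general affine map `b = M a + t` (a D x D
#' matrix plus translation: 12 free parameters in 3-D); `fit_affine4()` the
#' restricted map `b = beta a + t` with a single uniform scaling factor
#' (4 parameters in 3-D).  Both minimise the root-mean-squared Euclidean
#' colour error.
#'
#' The default `"closed_form"` solver finds the exact least-squares optimum.
#' `"simplex"` reproduces the historical iterative Nelder-Mead search from
#' seeded random starts (entries uniform in `[-1, 1]` around the identity /
#' zero), with `restarts` restarts and relative tolerance 1e-9; it exists as
#' a fidelity mode and can only do as well as the closed form.
#'
#' @param pairs a `color_pair_set` from [build_pairs()].
#' @param solver `"closed_form"` or `"simplex"`.
#' @param seed RNG seed for the simplex starts.
#' @param restarts number of simplex restarts.
#' @return An `affine_fit` with the fitted parameters, `rmse_model`,
#'   `rmse_identity` and `rrpe`.
#' @export
fit_affine12 <- function(pairs, solver = c("closed_form", "simplex"), seed = 1L,
                         restarts = 5L) {
  solver <- match.arg(solver)
  D <- pairs$dims
  if (nrow(pairs$a) <= D) stop("need more pairs than dimensions")
  if (solver == "closed_form") {
    X <- cbind(pairs$a, 1)
    qx <- qr(X)
    if (qx$rank < D + 1L) {
      warning("rank-deficient unfiltered colours: returning minimum-norm solution")
      cf <- svd_solve(X, pairs$b)
    } else {
      cf <- qr.coef(qx, pairs$b)
    }
    M <- t(cf[seq_len(D), , drop = FALSE])
    tvec <- cf[D + 1L, ]
    new_affine_fit("affine12", pairs, M = M, t = tvec)
  } else {
    obj <- function(par) {
      M <- matrix(par[seq_len(D * D)], D, D)
      tv <- par[D * D + seq_len(D)]
      pred <- pairs$a %*% t(M)
      pair_rmse(sweep(pred, 2L, tv, "+") - pairs$b)
    }
    par <- simplex_search(obj, seed, restarts, function() {
      c(as.numeric(diag(D)) + stats::runif(D * D, -1, 1), stats::runif(D, -1, 1))
    })
    new_affine_fit("affine12", pairs,
                   M = matrix(par[seq_len(D * D)], D, D),
                   t = par[D * D + seq_len(D)])
  }
}

svd_solve <- function(X, B, tol = 1e-10) {
  s <- svd(X)
  dinv <- ifelse(s$d > tol * max(s$d), 1 / s$d, 0)
  s$v %*% (dinv * (t(s$u) %*% B))
}

#' @rdname fit_affine12
#' @export
fit_affine4 <- function(pairs, solver = c("closed_form", "simplex"), seed = 1L,
                        restarts = 5L) {
  solver <- match.arg(solver)
  D <- pairs$dims
  if (nrow(pairs$a) <= D) stop("need more pairs than dimensions")
  if (solver == "closed_form") {
    # t drops out after centering; beta is a 1-D least-squares slope
    ac <- sweep(pairs$a, 2L, colMeans(pairs$a))
    bc <- sweep(pairs$b, 2L, colMeans(pairs$b))
    ss <- sum(ac^2)
    if (ss == 0) {
      warning("unfiltered colours are constant: beta indeterminate, using 0")
      beta <- 0
    } else {
      beta <- sum(ac * bc) / ss
    }
    tvec <- colMeans(pairs$b) - beta * colMeans(pairs$a)
    new_affine_fit("affine4", pairs, beta = beta, t = tvec)
  } else {
    obj <- function(par) {
      pair_rmse(sweep(pairs$a * par[1L], 2L, par[-1L], "+") - pairs$b)
    }
    par <- simplex_search(obj, seed, restarts, function() {
      c(1 + stats::runif(1, -1, 1), stats::runif(D, -1, 1))
    })
    new_affine_fit("affine4", pairs, beta = par[1L], t = par[-1L])
  }
}

simplex_search <- function(obj, seed, restarts, init) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- stats::optim(init(), obj, method = "Nelder-Mead",
                        control = list(maxit = 50000, reltol = 1e-9))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  best$par
}

#' Fit the "over" operator (partial-coverage model)
#'
#' Fits `C_filt = a * C_orig + (1 - a) * C_conv`, the convex special case of
#' the 4-parameter map in which scaling and translation are coupled through
#' a convergence colour.  Solved via [fit_affine4()] and re-parameterised as
#' `beta = a`, `C_conv = t / (1 - beta)`.  When `|1 - beta|` is below `tol`
#' the data describe a pure translation and no finite convergence point
#' exists; the fit is then flagged non-representable.
#'
#' @param pairs a `color_pair_set`.
#' @param tol threshold on `|1 - beta|` for representability.
#' @return An `affine_fit` with `family = "over"`, `c_conv`, and
#'   `representable`.
#' @export
fit_over <- function(pairs, tol = 1e-8) {
  f4 <- fit_affine4(pairs)
  beta <- f4$beta
  if (abs(1 - beta) < tol) {
    out <- new_affine_fit("over", pairs, beta = beta, t = f4$t,
                          c_conv = NULL, representable = FALSE)
  } else {
    out <- new_affine_fit("over", pairs, beta = beta, t = f4$t,
                          c_conv = f4$t / (1 - beta), representable = TRUE)
  }
  out
}

#' Full factorial convergence report
#'
#' Runs the affine fits over the full factorial of analysis conditions:
#' colour space (LMS, MB-DKL, CIELAB) x model family (12- vs 4-parameter) x
#' mask variant (full object / highlights excluded / all specular excluded)
#' x full-D vs isoluminant (MB-DKL and CIELAB only; declaring a luminance
#' axis in LMS would just re-create an opponent space) x dark-pixel
#' exclusion.  Failures are recorded per cell without aborting the table.
#'
#' @param scene a `synthetic_scene`, or a list with `unfiltered`, `filtered`
#'   and `masks$object` (optionally `masks$highlight`, `masks$specular`).
#' @param spaces,families condition levels.
#' @param solver,seed passed to the fitters.
#' @param cal,fundamentals colorimetry configuration.
#' @param dark_fraction dark-pixel luminance threshold fraction.
#' @return data.frame with one row per condition cell: the factors, RMSEs,
#'   `rrpe`, `n`, `ok` and `message`.
#' @export
converge_report <- function(scene, spaces = c("LMS", "MBDKL", "LAB"),
                            families = c("affine12", "affine4"),
                            solver = "closed_form", seed = 1L,
                            cal = default_monitor(),
                            fundamentals = cone_fundamentals(cal$grid),
                            dark_fraction = 0.05) {
  obj <- scene$masks$object
  hl <- scene$masks$highlight
  if (is.null(hl)) hl <- matrix(FALSE, nrow(obj), ncol(obj))
  spec <- scene$masks$specular
  if (is.null(spec)) spec <- hl
  masks <- list(full = obj, no_highlight = obj & !hl, no_specular = obj & !spec)
  dark <- dark_pixel_mask(scene$filtered, obj, hl, fraction = dark_fraction,
                          cal = cal)
  rows <- list()
  for (space in spaces) for (family in families) {
    for (mname in names(masks)) for (iso in c(FALSE, TRUE)) {
      if (iso && space == "LMS") next
      for (dex in c(FALSE, TRUE)) {
        cell <- tryCatch({
          pairs <- build_pairs(scene$unfiltered, scene$filtered, masks[[mname]],
                               space = space, isoluminant = iso,
                               exclude = if (dex) list(dark) else list(),
                               cal = cal, fundamentals = fundamentals)
          fit <- switch(family,
                        affine12 = fit_affine12(pairs, solver, seed),
                        affine4 = fit_affine4(pairs, solver, seed))
          data.frame(space = space, family = family, mask = mname,
                     isoluminant = iso, dark_excluded = dex,
                     rmse_model = fit$rmse_model,
                     rmse_identity = fit$rmse_identity,
                     rrpe = fit$rrpe, n = fit$n, ok = TRUE, message = "")
        }, error = function(e) {
          data.frame(space = space, family = family, mask = mname,
                     isoluminant = iso, dark_excluded = dex,
                     rmse_model = NA_real_, rmse_identity = NA_real_,
                     rrpe = NA_real_, n = NA_integer_, ok = FALSE,
                     message = conditionMessage(e))
        })
        rows[[length(rows) + 1L]] <- cell
      }
    }
  }
  do.call(rbind, rows)
}
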