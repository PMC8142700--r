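#' Gamut validation of observer settings
#'
#' A match setting passes iff every linear RGB component lies in `[0, 1]`
#' (boundary inclusive); out-of-gamut settings would be clamped or
#' mis-displayed by the monitor and are excluded from aggregation.
#'
#' @param setting RGB triplet or N x 3 matrix.
#' @return Logical vector, one entry per setting.
#' @export
validate_gamut <- function(setting) {
  m <- if (is.matrix(setting)) setting else matrix(setting, ncol = 3, byrow = TRUE)
  stopifnot(all(is.finite(m)))
  as.vector(rowSums(m >= 0 & m <= 1) == 3L)
}

#' Aggregate observer match records
#'
#' Two-level aggregation of colour-matching trials: out-of-gamut settings
#' are excluded first, then each observer's settings are averaged within a
#' stimulus, and the grand mean is the mean of the observers' means.  The
#' SEM (per LAB axis) and the 1-SEM covariance error ellipse in the
#' (a*, b*) plane are computed over the observer means.  A stimulus with no
#' surviving records is reported with `n_observers = 0`, not an error.
#'
#' @param records data.frame with columns `observer`, `stimulus`, `rep`,
#'   `R`, `G`, `B` and optionally `rating` (integer 1-5).
#' @param cal calibration used to convert settings to CIELAB.
#' @return List with `per_stimulus` (data.frame: grand mean LAB, SEM,
#'   n_observers, n_excluded, mean rating), `observer_means` (data.frame),
#'   and `ellipses` (per stimulus: 2x2 covariance of observer means in
#'   (a*, b*) scaled to 1 SEM, plus axis lengths and orientation).
#' @export
aggregate_matches <- function(records, cal = default_monitor()) {
  need <- c("observer", "stimulus", "rep", "R", "G", "B")
  stopifnot(all(need %in% names(records)))
  if ("rating" %in% names(records)) {
    ok_r <- is.na(records$rating) | (records$rating >= 1 & records$rating <= 5)
    if (!all(ok_r)) stop("quality ratings must lie in [1, 5]")
  }
  rgb <- as.matrix(records[, c("R", "G", "B")])
  in_gamut <- validate_gamut(rgb)
  excl_by_stim <- tapply(!in_gamut, records$stimulus, sum)
  kept <- records[in_gamut, , drop = FALSE]
  rgbk <- rgb[in_gamut, , drop = FALSE]

  lab <- if (nrow(rgbk)) {
    img <- matrix_to_image(rgbk, c(nrow(rgbk), 1L), "linearRGB")
    pixel_matrix(convert_space(img, "LAB", cal))
  } else {
    matrix(numeric(0), 0, 3)
  }

  key <- paste(kept$observer, kept$stimulus, sep = "\r")
  om <- if (nrow(lab)) {
    agg <- rowsum(lab, key) / as.vector(table(key))
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    data.frame(observer = parts[, 1], stimulus = parts[, 2],
               L = agg[, 1], a = agg[, 2], b = agg[, 3], row.names = NULL)
  } else {
    data.frame(observer = character(0), stimulus = character(0),
               L = numeric(0), a = numeric(0), b = numeric(0))
  }

  stimuli <- unique(as.character(records$stimulus))
  per <- lapply(stimuli, function(s) {
    oms <- om[om$stimulus == s, , drop = FALSE]
    n <- nrow(oms)
    nex <- if (s %in% names(excl_by_stim)) excl_by_stim[[s]] else 0L
    rating <- if ("rating" %in% names(kept)) {
      mean(kept$rating[kept$stimulus == s], na.rm = TRUE)
    } else NA_real_
    if (n == 0L) {
      return(data.frame(stimulus = s, L = NA, a = NA, b = NA,
                        sem_L = NA, sem_a = NA, sem_b = NA,
                        n_observers = 0L, n_excluded = nex, rating = rating))
    }
    gm <- colMeans(oms[, c("L", "a", "b")])
    sem <- if (n >= 2L) apply(oms[, c("L", "a", "b")], 2L, stats::sd) / sqrt(n) else rep(NA_real_, 3)
    data.frame(stimulus = s, L = gm[1], a = gm[2], b = gm[3],
               sem_L = sem[1], sem_a = sem[2], sem_b = sem[3],
               n_observers = n, n_excluded = nex, rating = rating)
  })
  ellipses <- lapply(stimuli, function(s) {
    oms <- om[om$stimulus == s, c("a", "b"), drop = FALSE]
    if (nrow(oms) < 2L) return(NULL)
    S <- stats::cov(as.matrix(oms)) / nrow(oms)   # covariance of the mean
    e <- eigen(S, symmetric = TRUE)
    list(cov = S, axes = sqrt(pmax(e$values, 0)),
         angle = atan2(e$vectors[2, 1], e$vectors[1, 1]))
  })
  names(ellipses) <- stimuli
  list(per_stimulus = do.call(rbind, per), observer_means = om,
       ellipses = ellipses)
}
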