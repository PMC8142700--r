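#' CIEDE2000 colour difference
#'
#' The CIE's recommended just-noticeable-difference metric for CIELAB, with
#' parametric factors kL = kC = kH = 1.  Symmetric, non-negative, and zero
#' exactly on identical inputs.  Vectorized: `lab1`/`lab2` may be triplets
#' or N x 3 matrices (recycled against each other row-wise).
#'
#' @param lab1,lab2 LAB triplets or N x 3 matrices.
#' @return Numeric vector of colour differences in JND units.
#' @export
ciede2000 <- function(lab1, lab2) {
  m1 <- if (is.matrix(lab1)) lab1 else matrix(lab1, ncol = 3, byrow = TRUE)
  m2 <- if (is.matrix(lab2)) lab2 else matrix(lab2, ncol = 3, byrow = TRUE)
  n <- max(nrow(m1), nrow(m2))
  if (nrow(m1) == 1L) m1 <- m1[rep(1L, n), , drop = FALSE]
  if (nrow(m2) == 1L) m2 <- m2[rep(1L, n), , drop = FALSE]
  stopifnot(nrow(m1) == nrow(m2), all(is.finite(m1)), all(is.finite(m2)))

  L1 <- m1[, 1]; a1 <- m1[, 2]; b1 <- m1[, 3]
  L2 <- m2[, 1]; a2 <- m2[, 2]; b2 <- m2[, 3]

  Cab <- (sqrt(a1^2 + b1^2) + sqrt(a2^2 + b2^2)) / 2
  G <- 0.5 * (1 - sqrt(Cab^7 / (Cab^7 + 25^7)))
  ap1 <- (1 + G) * a1
  ap2 <- (1 + G) * a2
  Cp1 <- sqrt(ap1^2 + b1^2)
  Cp2 <- sqrt(ap2^2 + b2^2)

  hp <- function(ap, b) {
    h <- atan2(b, ap) * 180 / pi
    ifelse(h < 0, h + 360, h)
  }
  hp1 <- ifelse(Cp1 == 0, 0, hp(ap1, b1))
  hp2 <- ifelse(Cp2 == 0, 0, hp(ap2, b2))

  dL <- L2 - L1
  dC <- Cp2 - Cp1
  dh <- hp2 - hp1
  dh <- ifelse(Cp1 * Cp2 == 0, 0,
        ifelse(dh > 180, dh - 360, ifelse(dh < -180, dh + 360, dh)))
  dH <- 2 * sqrt(Cp1 * Cp2) * sin(dh / 2 * pi / 180)

  Lbar <- (L1 + L2) / 2
  Cbar <- (Cp1 + Cp2) / 2
  hsum <- hp1 + hp2
  habs <- abs(hp1 - hp2)
  hbar <- ifelse(Cp1 * Cp2 == 0, hsum,
          ifelse(habs <= 180, hsum / 2,
          ifelse(hsum < 360, (hsum + 360) / 2, (hsum - 360) / 2)))

  t_ <- 1 - 0.17 * cos((hbar - 30) * pi / 180) +
            0.24 * cos(2 * hbar * pi / 180) +
            0.32 * cos((3 * hbar + 6) * pi / 180) -
            0.20 * cos((4 * hbar - 63) * pi / 180)
  dtheta <- 30 * exp(-((hbar - 275) / 25)^2)
  Rc <- 2 * sqrt(Cbar^7 / (Cbar^7 + 25^7))
  Sl <- 1 + 0.015 * (Lbar - 50)^2 / sqrt(20 + (Lbar - 50)^2)
  Sc <- 1 + 0.045 * Cbar
  Sh <- 1 + 0.015 * Cbar * t_
  Rt <- -sin(2 * dtheta * pi / 180) * Rc

  unname(sqrt((dL / Sl)^2 + (dC / Sc)^2 + (dH / Sh)^2 +
                Rt * (dC / Sc) * (dH / Sh)))
}
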