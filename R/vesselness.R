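# Multiscale Hessian tubular-structure enhancement (bright tubes on dark
# background), used to sharpen the small-vessel segmentation before
# skeletonization.

# Shift an array along one axis with edge replication.
.shiftArray <- function(a, axis, by) {
  d <- dim(a)
  idx <- lapply(d, seq_len)
  src <- pmin(pmax(idx[[axis]] - by, 1L), d[axis])
  idx[[axis]] <- src
  do.call(`[`, c(list(a), idx))
}

# Separable convolution along one axis with a symmetric kernel.
.convAxis <- function(a, kernel, axis) {
  half <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(a))
  for (i in seq_along(kernel))
    out <- out + kernel[i] * .shiftArray(a, axis, i - half - 1L)
  out
}

gaussSmooth3d <- function(a, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  for (axis in 1:3) a <- .convAxis(a, k, axis)
  a
}

# Eigenvalues of voxelwise symmetric 3x3 Hessians, vectorized (trigonometric
# closed form); returns a 3-column matrix sorted by |lambda| ascending.
.symEigen3 <- function(a11, a22, a33, a12, a13, a23) {
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a13^2 + a23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p < 1e-12
  ps <- ifelse(iso, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  phi <- acos(pmin(1, pmax(-1, detB / 2))) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  ev <- cbind(e1, e2, e3)
  ev[iso, ] <- q[iso]
  # sort rows by |lambda| ascending
  ord <- t(apply(abs(ev), 1, order))
  n <- nrow(ev)
  cbind(ev[cbind(1:n, ord[, 1])], ev[cbind(1:n, ord[, 2])],
        ev[cbind(1:n, ord[, 3])])
}

#' Multiscale Hessian vesselness filter
#'
#' Tube-likeness measure from the eigenvalues of the scale-normalized
#' Gaussian Hessian (bright-tube polarity: the two large eigenvalues must be
#' negative), taking the maximum response over scales. Used to enhance small
#' vessels in the CD angiogram before thresholding.
#'
#' @param cd [VolumeGrid-class] or 3D array.
#' @param scales Gaussian scales in voxels (default 0.5-1.5).
#' @param alpha,beta plate/blob discrimination constants.
#' @param gamma structureness constant; NULL = half the maximum Frobenius
#'   norm (per scale).
#' @return 3D array of vesselness in [0, 1].
#' @export
hessianVesselness <- function(cd, scales = c(0.5, 1.0, 1.5), alpha = 0.5,
                              beta = 0.5, gamma = NULL) {
  a <- if (is(cd, "VolumeGrid")) voxelData(cd) else cd
  best <- array(0, dim(a))
  d1 <- c(-0.5, 0, 0.5)
  d2 <- c(1, -2, 1)
  for (s in scales) {
    sm <- gaussSmooth3d(a, s)
    h11 <- .convAxis(sm, d2, 1); h22 <- .convAxis(sm, d2, 2)
    h33 <- .convAxis(sm, d2, 3)
    h12 <- .convAxis(.convAxis(sm, d1, 1), d1, 2)
    h13 <- .convAxis(.convAxis(sm, d1, 1), d1, 3)
    h23 <- .convAxis(.convAxis(sm, d1, 2), d1, 3)
    norm <- s^2                               # gamma-normalized derivatives
    ev <- .symEigen3(as.numeric(h11) * norm, as.numeric(h22) * norm,
                     as.numeric(h33) * norm, as.numeric(h12) * norm,
                     as.numeric(h13) * norm, as.numeric(h23) * norm)
    l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
    S <- sqrt(l1^2 + l2^2 + l3^2)
    cc <- if (is.null(gamma)) max(S) / 2 else gamma
    if (cc <= 0) cc <- 1
    ra <- abs(l2) / pmax(abs(l3), 1e-12)
    rb <- abs(l1) / pmax(sqrt(abs(l2 * l3)), 1e-12)
    v <- (1 - exp(-ra^2 / (2 * alpha^2))) * exp(-rb^2 / (2 * beta^2)) *
      (1 - exp(-S^2 / (2 * cc^2)))
    v[l2 > 0 | l3 > 0] <- 0                   # bright-tube polarity
    best <- pmax(best, array(v, dim(a)))
  }
  best
}
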