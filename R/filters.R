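# Signal utilities for the normative-connectome preprocessing chain:
# Butterworth band-pass design (bilinear transform), zero-phase filtering,
# separable 3-D Gaussian smoothing, and Power-convention framewise
# displacement. No signal-processing package is available in the
# deployment environment, so the small pieces needed are implemented here.

.poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (rt in r) p <- c(p, 0 + 0i) - c(0 + 0i, p * rt)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' Order-2 prototype (4 poles after the band transform) by default,
#' matching the conventional resting-state 0.01-0.08 Hz filter.
#'
#' @param low,high band edges in Hz
#' @param fs sampling frequency in Hz
#' @param order prototype order
#' @return list with numerator `b` and denominator `a` coefficients
#' @export
butter_bandpass <- function(low, high, fs, order = 2) {
  stopifnot(low > 0, high > low, high < fs / 2)
  n <- order
  k <- seq_len(n)
  p <- exp(1i * pi * (2 * k + n - 1) / (2 * n))   # analog lowpass prototype
  gain <- 1
  # prewarp band edges (normalized sampling rate 2)
  w1 <- 4 * tan(pi * low / fs)
  w2 <- 4 * tan(pi * high / fs)
  bw <- w2 - w1
  wo <- sqrt(w1 * w2)
  # lowpass -> bandpass in zpk form
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- rep(0 + 0i, n)
  gain <- gain * bw^n
  # bilinear transform at fs_ = 2
  fs2 <- 4
  z_d <- (fs2 + z_bp) / (fs2 - z_bp)
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  z_d <- c(z_d, rep(-1 + 0i, length(p_bp) - length(z_bp)))
  gain <- gain * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(gain * .poly_from_roots(z_d))
  a <- Re(.poly_from_roots(p_d))
  list(b = b, a = a)
}

# steady-state filter state for a unit-step input; scaled by each
# column's first sample it starts the forward pass transient-free
.lfilter_zi <- function(b, a) {
  b <- b / a[1]; a <- a / a[1]
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  A <- rbind(-a[2:n], cbind(diag(n - 2), 0))
  B <- b[2:n] - a[2:n] * b[1]
  solve(diag(n - 1) - t(A), B)
}

#' Zero-phase (forward-backward) filtering
#'
#' Applies the filter forward and backward with odd-reflection edge
#' padding, so the passband incurs no phase shift.
#'
#' @param b,a filter coefficients from [butter_bandpass()]
#' @param x numeric vector, or a time x series matrix filtered column-wise
#' @export
filtfilt_sm <- function(b, a, x) {
  was_vec <- is.null(dim(x))
  if (was_vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  npad <- 3 * max(length(a), length(b))
  if (n <= npad)
    stop("series too short for zero-phase filtering (need > ", npad, " points)")
  head_pad <- 2 * matrix(x[1, ], npad, ncol(x), byrow = TRUE) -
    x[(npad + 1):2, , drop = FALSE]
  tail_pad <- 2 * matrix(x[n, ], npad, ncol(x), byrow = TRUE) -
    x[(n - 1):(n - npad), , drop = FALSE]
  xp <- rbind(head_pad, x, tail_pad)
  zi <- .lfilter_zi(b, a)
  y <- iir_filter_cpp(b, a, xp, zi, xp[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- iir_filter_cpp(b, a, y, zi, y[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(npad + 1):(npad + n), , drop = FALSE]
  if (was_vec) as.numeric(out) else out
}

.gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

.smooth_matrix <- function(d, sigma_vox) {
  k <- .gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1) / 2
  S <- matrix(0, d, d)
  for (i in seq_len(d)) {
    j <- (i - r):(i + r)
    keep <- j >= 1 & j <= d
    S[i, j[keep]] <- k[keep]
  }
  S
}

.apply_axis <- function(arr, S, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  m <- matrix(aperm(arr, perm), nrow = d[axis])
  out <- S %*% m
  aperm(array(out, dim = d[perm]), order(perm))
}

#' Separable 3-D Gaussian smoothing
#'
#' Smooths the three spatial axes of a 3-D or 4-D array with a truncated
#' (3 sigma) Gaussian, zero-padded at the edges.
#'
#' @param arr 3-D array or 4-D array (x, y, z, time)
#' @param fwhm_mm kernel full width at half maximum in mm
#' @param voxel_mm voxel edge lengths (scalar or 3-vector)
#' @export
gaussian_smooth <- function(arr, fwhm_mm, voxel_mm) {
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  for (axis in 1:3) {
    if (sigma[axis] <= 0) next
    S <- .smooth_matrix(dim(arr)[axis], sigma[axis])
    arr <- .apply_axis(arr, S, axis)
  }
  arr
}

#' Framewise displacement (Power convention)
#'
#' Sum of absolute backward differences of the six rigid-body parameters,
#' with rotations (radians) converted to arc length on a 50 mm sphere.
#' The first frame has FD = 0.
#'
#' @param motion time x 6 matrix: 3 translations (mm), 3 rotations (rad)
#' @param rotation_radius_mm sphere radius for the rotation conversion
#' @return numeric vector of per-frame FD in mm
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  stopifnot(ncol(motion) == 6)
  d <- rbind(rep(0, 6), abs(diff(as.matrix(motion))))
  d[, 4:6] <- d[, 4:6] * rotation_radius_mm
  rowSums(d)
}
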