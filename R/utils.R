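# Shared numeric helpers.

# FWHM of a Gaussian = 2 sqrt(2 ln 2) sigma
FWHM_PER_SIGMA <- 2 * sqrt(2 * log(2))

#' @keywords internal
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_PER_SIGMA

#' @keywords internal
sigma_to_fwhm <- function(sigma) sigma * FWHM_PER_SIGMA

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name, zero_ok = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (if (zero_ok) x < 0 else x <= 0)) {
    stop(sprintf("`%s` must be a single finite %s number", name,
                 if (zero_ok) "nonnegative" else "positive"), call. = FALSE)
  }
  invisible(x)
}

# 1-D Gaussian kernel, truncated at +/- 4 sigma, unit sum.
gauss_kernel_1d <- function(sigma_px, truncate = 4) {
  if (sigma_px <= 0) return(1)
  half <- max(1L, ceiling(truncate * sigma_px))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a matrix. The kernel is renormalized where
# it is truncated by the image border, so a flat image stays exactly flat and
# interior mass is conserved.
gauss_blur_matrix <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  k <- gauss_kernel_1d(sigma_px)
  m2 <- conv_sep_1d(m, k, along = 1L)
  conv_sep_1d(m2, k, along = 2L)
}

# Convolve each column (along = 1) or row (along = 2) of `m` with kernel `k`,
# renormalizing the kernel at the borders. Implemented as a banded matrix
# product so frames of a movie can be filtered quickly.
conv_sep_1d <- function(m, k, along = 1L) {
  n <- if (along == 1L) nrow(m) else ncol(m)
  half <- (length(k) - 1L) %/% 2L
  # Banded convolution matrix with border renormalization.
  cm <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - half):(j + half)
    keep <- idx >= 1L & idx <= n
    w <- k[keep]
    cm[idx[keep], j] <- w / sum(w)
  }
  if (along == 1L) t(cm) %*% m else m %*% cm
}

# Linear interpolation of a matrix at fractional (row, col) positions.
bilinear_at <- function(m, rows, cols) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- pmin(pmax(rows, 1), nr)
  cols <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(rows), nr - 1L); c0 <- pmin(floor(cols), nc - 1L)
  fr <- rows - r0; fc <- cols - c0
  m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    m[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
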