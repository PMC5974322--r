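# Registration, spatial filtering and temporal resampling of movie stacks.

# Integer-pixel shift of a matrix with edge replication.
shift_matrix <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  src_r <- pmin(pmax(seq_len(h) - dy, 1L), h)
  src_c <- pmin(pmax(seq_len(w) - dx, 1L), w)
  m[src_r, src_c, drop = FALSE]
}

# Cross-correlation (FFT) translation of `frame` relative to `ref`, with
# parabolic sub-pixel refinement. Positive dy/dx mean the frame content is
# displaced down/right relative to the reference.
cc_shift <- function(ref, frame, max_shift) {
  h <- nrow(ref); w <- ncol(ref)
  r <- ref - mean(ref); f <- frame - mean(frame)
  cc <- Re(stats::fft(Conj(stats::fft(r)) * stats::fft(f), inverse = TRUE)) / (h * w)
  # wrapped lags; restrict the search to +/- max_shift
  lag_r <- c(0:(h - 1)); lag_r[lag_r > h / 2] <- lag_r[lag_r > h / 2] - h
  lag_c <- c(0:(w - 1)); lag_c[lag_c > w / 2] <- lag_c[lag_c > w / 2] - w
  ok <- outer(abs(lag_r) <= max_shift, abs(lag_c) <= max_shift, `&`)
  cc[!ok] <- -Inf
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  dy <- lag_r[pk[1]]; dx <- lag_c[pk[2]]
  # parabolic refinement using wrapped neighbours
  para <- function(cm1, c0, cp1) {
    den <- cm1 - 2 * c0 + cp1
    if (!is.finite(den) || den == 0) 0 else 0.5 * (cm1 - cp1) / den
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  ddy <- para(cc[wrap(pk[1] - 1, h), pk[2]], cc[pk[1], pk[2]],
              cc[wrap(pk[1] + 1, h), pk[2]])
  ddx <- para(cc[pk[1], wrap(pk[2] - 1, w)], cc[pk[1], pk[2]],
              cc[pk[1], wrap(pk[2] + 1, w)])
  c(dy + ddy, dx + ddx)
}

#' Rigid (translation) registration of a movie stack
#'
#' Estimates a per-frame XY translation maximizing the cross-correlation
#' with a reference image, refines it to sub-pixel precision by parabolic
#' interpolation of the correlation peak, and corrects each frame by the
#' rounded shift with edge replication. Shifts are reported at sub-pixel
#' resolution.
#'
#' @param movie a [movie_stack()] with at least 1 frame.
#' @param reference `"mean"` (time-averaged image) or a frame index.
#' @param max_shift_px largest plausible displacement searched, pixels.
#' @return a list with `movie` (corrected [movie_stack()]) and `shifts`
#'   (tibble: `frame`, `dy_px`, `dx_px`).
#' @export
register_rigid <- function(movie, reference = "mean", max_shift_px = 10) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  ref <- if (identical(reference, "mean")) mean_image(movie)
         else movie$data[reference, , ]
  shifts <- matrix(0, d[1], 2)
  out <- movie$data
  if (d[1] >= 2L) {
    for (t in seq_len(d[1])) {
      fr <- movie$data[t, , ]
      if (all(fr == 0)) {
        warning(sprintf("frame %d is all-zero; shift set to 0", t),
                call. = FALSE)
        next
      }
      s <- cc_shift(ref, fr, max_shift_px)
      shifts[t, ] <- s
      si <- round(s)
      if (any(si != 0)) out[t, , ] <- shift_matrix(fr, -si[1], -si[2])
    }
  }
  corrected <- movie
  corrected$data <- out
  list(
    movie = corrected,
    shifts = tibble::tibble(frame = seq_len(d[1]),
                            dy_px = shifts[, 1], dx_px = shifts[, 2])
  )
}

#' Per-frame Gaussian spatial filtering
#'
#' Smooths each frame with a separable Gaussian kernel whose sigma is given
#' in micrometres and converted to pixels through the movie calibration.
#' The kernel is renormalized at the image borders, so total intensity of an
#' interior spot is conserved. `sigma_um = 0` returns the input unchanged.
#'
#' @param movie a [movie_stack()].
#' @param sigma_um Gaussian sigma in micrometres (`>= 0`).
#' @return the filtered [movie_stack()].
#' @export
spatial_filter <- function(movie, sigma_um = 0.2) {
  stopifnot(inherits(movie, "movie_stack"))
  assert_scalar_pos(sigma_um, "sigma_um", zero_ok = TRUE)
  if (sigma_um == 0) return(movie)
  sigma_px <- sigma_um / movie$um_per_px
  d <- dim(movie$data)
  k <- gauss_kernel_1d(sigma_px)
  if (length(k) == 1L) return(movie)
  out <- movie$data
  for (t in seq_len(d[1])) {
    out[t, , ] <- gauss_blur_matrix(movie$data[t, , ], sigma_px)
  }
  movie$data <- out
  movie
}

#' Temporal resampling by block averaging
#'
#' Averages non-overlapping blocks of `round(fps / target_fps)` consecutive
#' frames; a trailing partial block is dropped. The output frame rate is
#' `fps / block`, which equals `target_fps` when the rates divide evenly.
#'
#' @param movie a [movie_stack()].
#' @param target_fps requested output frame rate (`<= fps`).
#' @return the resampled [movie_stack()].
#' @examples
#' mov <- movie_stack(array(1, c(20, 4, 4)), fps = 60, um_per_px = 1)
#' n_frames(temporal_resample(mov, 6))  # blocks of 10 -> 2 frames
#' @export
temporal_resample <- function(movie, target_fps = 6) {
  stopifnot(inherits(movie, "movie_stack"))
  assert_scalar_pos(target_fps, "target_fps")
  if (target_fps > movie$fps) {
    stop("`target_fps` must not exceed the movie frame rate", call. = FALSE)
  }
  block <- max(1L, round(movie$fps / target_fps))
  if (block == 1L) return(movie)
  d <- dim(movie$data)
  n_out <- d[1] %/% block
  if (n_out < 1L) stop("movie shorter than one resampling block", call. = FALSE)
  keep <- seq_len(n_out * block)
  m <- matrix(movie$data[keep, , ], n_out * block, d[2] * d[3])
  grp <- rep(seq_len(n_out), each = block)
  res <- rowsum(m, grp) / block
  movie$data <- array(res, c(n_out, d[2], d[3]))
  movie$fps <- movie$fps / block
  movie
}
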