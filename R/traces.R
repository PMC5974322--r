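# Per-ROI trace extraction, percentile baseline, dF/F and ROI-area metrics.

#' Raw fluorescence traces of a set of ROIs
#'
#' For each ROI the trace at time `t` is the mean, over the pixels in the
#' footprint support, of `a_i(p) * movie(t, p)` — the footprint-weighted
#' movie averaged over the support. Linear in the movie intensities.
#'
#' @param movie a [movie_stack()] with the same geometry as `rois`.
#' @param rois a [roi_set].
#' @return a tibble with columns `roi`, `frame`, `time_s`, `f_roi`.
#' @export
roi_fluorescence <- function(movie, rois) {
  stopifnot(inherits(movie, "movie_stack"), inherits(rois, "roi_set"))
  d <- dim(movie$data)
  if (d[2] != rois$dims[1] || d[3] != rois$dims[2]) {
    stop("movie and roi_set geometry differ", call. = FALSE)
  }
  Y <- movie_matrix(movie)
  K <- n_rois(rois)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    a <- rois$spatial[, k]
    sup <- which(a > 0)
    tr <- crossprod(a[sup], Y[sup, , drop = FALSE])[1, ] / length(sup)
    out[[k]] <- tibble::tibble(
      roi = k, frame = seq_len(d[1]),
      time_s = (seq_len(d[1]) - 1) / movie$fps, f_roi = tr
    )
  }
  dplyr::bind_rows(out)
}

#' Percentile baseline of a fluorescence trace
#'
#' The baseline fluorescence F is the 8th percentile of the trace, either in
#' a sliding window of `± window_s` seconds around each time point
#' (truncated at the edges) or over the whole trace (a scalar broadcast to
#' the trace length). Percentiles use linear interpolation between order
#' statistics.
#'
#' @param trace numeric fluorescence series (length `>= 2`).
#' @param fps frame rate of the trace.
#' @param mode `"sliding"` or `"whole"`.
#' @param window_s half-width of the sliding window, seconds.
#' @param percentile baseline percentile as a fraction (default 0.08).
#' @return numeric baseline series, same length as `trace`.
#' @export
baseline_f <- function(trace, fps, mode = c("sliding", "whole"),
                       window_s = 15, percentile = 0.08) {
  mode <- match.arg(mode)
  if (length(trace) < 2L) stop("trace length must be >= 2", call. = FALSE)
  assert_scalar_pos(fps, "fps")
  if (mode == "whole") {
    return(rep(stats::quantile(trace, percentile, names = FALSE),
               length(trace)))
  }
  half <- max(1L, round(window_s * fps))
  n <- length(trace)
  vapply(seq_len(n), function(t) {
    idx <- max(1L, t - half):min(n, t + half)
    stats::quantile(trace[idx], percentile, names = FALSE)
  }, numeric(1))
}

#' Relative fluorescence change dF/F
#'
#' `(trace - baseline) / baseline`. The baseline must be strictly positive
#' everywhere; a nonpositive value raises an error naming the first
#' offending index.
#'
#' @param trace fluorescence series.
#' @param baseline baseline series of equal length (or scalar).
#' @return dF/F series.
#' @examples
#' dff(c(100, 120, 200), 100)  # 0, 0.2, 1
#' @export
dff <- function(trace, baseline) {
  baseline <- rep_len(baseline, length(trace))
  bad <- which(baseline <= 0)
  if (length(bad)) {
    stop(sprintf("baseline is not positive at index %d", bad[1]), call. = FALSE)
  }
  (trace - baseline) / baseline
}

#' Area and equivalent diameter of extracted ROIs
#'
#' The ROI area is the set of pixels where the max-normalized footprint
#' exceeds `threshold` (default 0.5); its equivalent diameter is that of the
#' circle of equal area, `2 sqrt(area / pi)`. ROIs whose centre lies within
#' `edge_margin_um` of the field edge are flagged for exclusion. Both
#' metrics are invariant under any positive rescaling of the footprint.
#'
#' @param rois a [roi_set].
#' @param threshold half-maximum threshold on the normalized footprint.
#' @param edge_margin_um exclusion margin from the field edge, micrometres.
#' @return tibble: `roi`, `n_pixels`, `area_um2`, `diameter_um`,
#'   `edge_excluded`.
#' @export
roi_area_metrics <- function(rois, threshold = 0.5, edge_margin_um = 4) {
  stopifnot(inherits(rois, "roi_set"))
  up <- rois$um_per_px
  margin_px <- edge_margin_um / up
  K <- n_rois(rois)
  n_px <- integer(K)
  for (k in seq_len(K)) {
    a <- rois$spatial[, k]
    n_px[k] <- sum(a / max(a) > threshold)
  }
  ctr <- rois$centers
  edge <- ctr$row <= margin_px | ctr$row > rois$dims[1] - margin_px |
          ctr$col <= margin_px | ctr$col > rois$dims[2] - margin_px
  tibble::tibble(
    roi = seq_len(K), n_pixels = n_px,
    area_um2 = n_px * up^2,
    diameter_um = 2 * sqrt(n_px * up^2 / pi),
    edge_excluded = edge
  )
}

#' Centre-aligned average ROI image and line profile
#'
#' Crops a square of half-width `half_width_px` around each ROI centre,
#' averages the max-normalized footprints, and returns the mean image with
#' the profile along its central row.
#'
#' @param rois a [roi_set] with at least one ROI.
#' @param half_width_px crop half-width in pixels.
#' @return list with `image` (`(2h+1) x (2h+1)` matrix) and `profile`
#'   (tibble: `offset_px`, `offset_um`, `value`).
#' @export
average_roi_image <- function(rois, half_width_px = 8L) {
  stopifnot(inherits(rois, "roi_set"))
  K <- n_rois(rois)
  if (K < 1L) stop("at least one ROI is required", call. = FALSE)
  hw <- as.integer(half_width_px)
  sz <- 2L * hw + 1L
  acc <- matrix(0, sz, sz)
  cnt <- matrix(0, sz, sz)
  for (k in seq_len(K)) {
    img <- roi_footprint(rois, k)
    img <- img / max(img)
    r0 <- rois$centers$row[k]; c0 <- rois$centers$col[k]
    for (dr in -hw:hw) {
      r <- r0 + dr
      if (r < 1L || r > nrow(img)) next
      cols <- (c0 - hw):(c0 + hw)
      ok <- cols >= 1L & cols <= ncol(img)
      acc[dr + hw + 1L, which(ok)] <- acc[dr + hw + 1L, which(ok)] + img[r, cols[ok]]
      cnt[dr + hw + 1L, which(ok)] <- cnt[dr + hw + 1L, which(ok)] + 1
    }
  }
  avg <- acc / pmax(cnt, 1)
  prof <- avg[hw + 1L, ]
  list(
    image = avg,
    profile = tibble::tibble(
      offset_px = -hw:hw,
      offset_um = (-hw:hw) * rois$um_per_px,
      value = prof
    )
  )
}

#' Spike-event rate of an event series
#'
#' Counts time bins whose event amplitude exceeds `threshold` and converts
#' to events per minute.
#'
#' @param events nonnegative event series (one ROI).
#' @param duration_s duration covered by the series, seconds (`> 0`).
#' @param threshold amplitude threshold (`> threshold` counts as an event).
#' @return events per minute.
#' @examples
#' spike_event_rate(rep(c(1, 0), c(327, 273)), duration_s = 600)  # 32.7
#' @export
spike_event_rate <- function(events, duration_s, threshold = 0) {
  assert_scalar_pos(duration_s, "duration_s")
  if (length(events) == 0L) return(0)
  sum(events > threshold) * 60 / duration_s
}
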