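# Neuropil decontamination: surround traces, robust contamination slopes,
# and the field-wide median correction.

# Binary dilation of a pixel mask by a circular structuring element.
dilate_mask <- function(mask, radius_px) {
  h <- nrow(mask); w <- ncol(mask)
  r <- ceiling(radius_px)
  out <- matrix(FALSE, h, w)
  offs <- expand.grid(dy = -r:r, dx = -r:r)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius_px^2, ]
  idx <- which(mask, arr.ind = TRUE)
  for (i in seq_len(nrow(offs))) {
    rr <- idx[, 1] + offs$dy[i]
    cc <- idx[, 2] + offs$dx[i]
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    out[cbind(rr[ok], cc[ok])] <- TRUE
  }
  out
}

#' Surround (neuropil) fluorescence trace of an ROI
#'
#' The neuropil trace is the per-frame mean intensity over the pixels within
#' `radius_um` of the ROI support but outside the support itself — an
#' annulus, so the ROI's own pixels never regress on themselves.
#'
#' @param movie a [movie_stack()].
#' @param roi_spatial the ROI footprint: an `H x W` matrix (or a vector of
#'   length `H * W`); pixels with value `> 0` form the support.
#' @param radius_um annulus outer radius measured from the support,
#'   micrometres.
#' @return numeric trace of length `n_frames(movie)`.
#' @export
neuropil_trace <- function(movie, roi_spatial, radius_um = 2) {
  stopifnot(inherits(movie, "movie_stack"))
  assert_scalar_pos(radius_um, "radius_um")
  d <- dim(movie$data)
  support <- matrix(as.vector(roi_spatial) > 0, d[2], d[3])
  if (!any(support)) stop("ROI support is empty", call. = FALSE)
  ring <- dilate_mask(support, radius_um / movie$um_per_px) & !support
  if (!any(ring)) {
    stop("neuropil neighborhood is empty (ROI fills the field)", call. = FALSE)
  }
  Y <- movie_matrix(movie)
  colMeans(Y[as.vector(ring), , drop = FALSE])
}

#' Contamination factor of one ROI by robust regression
#'
#' Time points where the ROI trace exceeds its mean plus
#' `sd_multiplier` standard deviations (calcium transients) are dropped;
#' on the remaining points the slope of a robust linear regression of
#' `f_roi` on `f_neuropil` — iteratively re-weighted least squares with
#' bisquare weights (tuning constant 4.685) that discount large deviations —
#' is the contamination factor. An intercept is included but only the slope
#' is used. Use `sd_multiplier = 2` for spinning-disk data and `1` for
#' two-photon data.
#'
#' @param f_roi,f_neuropil aligned fluorescence series.
#' @param sd_multiplier transient-exclusion threshold in SD units.
#' @return the contamination slope (scalar).
#' @export
contamination_factor <- function(f_roi, f_neuropil, sd_multiplier = 2) {
  if (length(f_roi) != length(f_neuropil)) {
    stop("series must be aligned (equal length)", call. = FALSE)
  }
  keep <- f_roi <= mean(f_roi) + sd_multiplier * stats::sd(f_roi)
  if (sum(keep) < 20L) {
    stop("fewer than 20 time points retained after transient exclusion",
         call. = FALSE)
  }
  x <- f_neuropil[keep]; y <- f_roi[keep]
  if (stats::sd(x) == 0) {
    stop("neuropil trace has zero variance; slope undefined", call. = FALSE)
  }
  # an exactly linear relation makes the IRLS scale collapse; the slope is
  # still right, so the non-convergence warning is noise here
  fit <- suppressWarnings(
    MASS::rlm(y ~ x, psi = MASS::psi.bisquare, c = 4.685, maxit = 100)
  )
  unname(stats::coef(fit)[2])
}

#' Subtract scaled neuropil contamination from an ROI trace
#'
#' `f_true = f_roi - r_global * f_neuropil`, linear in both inputs. The
#' field-wide factor `r_global` is conventionally the median of the per-ROI
#' contamination slopes of that imaging field (see [trace_bundle()]).
#'
#' @param f_roi,f_neuropil aligned fluorescence series.
#' @param r_global contamination factor (finite scalar).
#' @return decontaminated series `f_true`.
#' @export
decontaminate <- function(f_roi, f_neuropil, r_global) {
  if (!is.finite(r_global)) stop("`r_global` must be finite", call. = FALSE)
  f_roi - r_global * f_neuropil
}

#' Build a full trace bundle for an imaging field
#'
#' Runs the complete per-ROI trace pipeline for an extracted field: raw ROI
#' traces, surround neuropil traces, per-ROI contamination slopes, the
#' field-wide median slope `r_global`, decontaminated traces, percentile
#' baselines and dF/F.
#'
#' @param movie a registered [movie_stack()] (the one the traces should be
#'   measured on).
#' @param rois a [roi_set] for the same geometry.
#' @param radius_um neuropil annulus radius, micrometres.
#' @param sd_multiplier transient-exclusion threshold (see
#'   [contamination_factor()]).
#' @param baseline_mode,window_s,percentile baseline options, see
#'   [baseline_f()].
#' @return an object of class `trace_bundle`: list with `traces` (tibble:
#'   `roi`, `frame`, `time_s`, `f_roi`, `f_neuropil`, `f_true`, `baseline`,
#'   `dff`), `r` (tibble: `roi`, `r_i`) and `r_global`.
#' @export
trace_bundle <- function(movie, rois, radius_um = 2, sd_multiplier = 2,
                         baseline_mode = "whole", window_s = 15,
                         percentile = 0.08) {
  stopifnot(inherits(rois, "roi_set"))
  K <- n_rois(rois)
  if (K < 1L) stop("roi_set has no ROIs", call. = FALSE)
  tr <- roi_fluorescence(movie, rois)
  np <- vector("list", K)
  r_i <- numeric(K)
  for (k in seq_len(K)) {
    fnp <- neuropil_trace(movie, rois$spatial[, k], radius_um)
    froi <- tr$f_roi[tr$roi == k]
    r_i[k] <- tryCatch(
      contamination_factor(froi, fnp, sd_multiplier),
      error = function(e) NA_real_
    )
    np[[k]] <- fnp
  }
  r_global <- stats::median(r_i, na.rm = TRUE)
  traces <- tr %>%
    dplyr::group_by(.data$roi) %>%
    dplyr::group_modify(function(g, key) {
      fnp <- np[[key$roi]]
      ftrue <- decontaminate(g$f_roi, fnp, r_global)
      bl <- baseline_f(ftrue, fps = 1 / (g$time_s[2] - g$time_s[1]),
                       mode = baseline_mode, window_s = window_s,
                       percentile = percentile)
      dplyr::mutate(g, f_neuropil = fnp, f_true = ftrue, baseline = bl,
                    dff = dff(ftrue, pmax(bl, .Machine$double.eps)))
    }) %>%
    dplyr::ungroup()
  structure(
    list(traces = traces,
         r = tibble::tibble(roi = seq_len(K), r_i = r_i),
         r_global = r_global),
    class = "trace_bundle"
  )
}

#' @export
print.trace_bundle <- function(x, ...) {
  cat(sprintf("<trace_bundle> %d ROI(s), %d frame(s) | r_global = %.3f\n",
              nrow(x$r), max(x$traces$frame), x$r_global))
  invisible(x)
}
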