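# broom-style tidy()/glance() methods for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy psf_fit
#' @export
tidy.psf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("center", "sigma", "fwhm", "amplitude", "offset"),
    estimate = c(x$center, x$sigma, x$fwhm, x$amplitude, x$offset)
  )
}

#' @method glance psf_fit
#' @export
glance.psf_fit <- function(x, ...) {
  tibble::tibble(fwhm = x$fwhm, sigma = x$sigma,
                 residual_rms = x$residual_rms, converged = x$converged)
}

#' @method tidy noise_model_fit
#' @export
tidy.noise_model_fit <- function(x, ...) x$pixel_stats

#' @method glance noise_model_fit
#' @export
glance.noise_model_fit <- function(x, ...) {
  tibble::tibble(nr = x$nr, intercept = x$intercept, n_pixels = x$n_pixels)
}

#' @method tidy roi_set
#' @export
tidy.roi_set <- function(x, ...) {
  if (n_rois(x) == 0L) return(tibble::tibble(roi = integer()))
  dplyr::left_join(x$centers, roi_area_metrics(x, ...), by = "roi")
}

#' @method glance roi_set
#' @export
glance.roi_set <- function(x, ...) {
  tibble::tibble(
    n_rois = n_rois(x), height_px = x$dims[1], width_px = x$dims[2],
    n_frames = ncol(x$temporal), fps = x$fps, um_per_px = x$um_per_px
  )
}

#' @method tidy trace_bundle
#' @export
tidy.trace_bundle <- function(x, ...) x$traces

#' @method glance trace_bundle
#' @export
glance.trace_bundle <- function(x, ...) {
  tibble::tibble(n_rois = nrow(x$r), r_global = x$r_global,
                 n_frames = max(x$traces$frame))
}

#' @method tidy pairwise_corr
#' @export
tidy.pairwise_corr <- function(x, ...) x$histogram

#' @method glance pairwise_corr
#' @export
glance.pairwise_corr <- function(x, ...) {
  tibble::tibble(n_rois = nrow(x$matrix), n_pairs = length(x$values),
                 median_corr = stats::median(x$values),
                 mean_corr = mean(x$values))
}

#' @method tidy degradation_study
#' @export
tidy.degradation_study <- function(x, ...) x$ratios

#' @method tidy overlap_report
#' @export
tidy.overlap_report <- function(x, ...) x$pairs

#' @method glance overlap_report
#' @export
glance.overlap_report <- function(x, ...) {
  tibble::tibble(n_rois = x$n_rois, n_overlapping = x$n_overlapping,
                 n_excluded_pairs = nrow(x$excluded_pairs),
                 overlap_ratio = x$overlap_ratio)
}

#' @method tidy ground_truth
#' @export
tidy.ground_truth <- function(x, ...) x$boutons

#' @method glance ground_truth
#' @export
glance.ground_truth <- function(x, ...) {
  tibble::tibble(
    n_axons = length(x$arbors), n_boutons = nrow(x$boutons),
    field_x_um = x$field_um[1], field_y_um = x$field_um[2],
    duration_s = x$duration_s, fps = x$fps, seed = x$seed
  )
}
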