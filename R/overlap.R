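# Multi-plane ROI overlap analysis: how often do ROIs from axially adjacent
# imaging planes occupy the same lateral footprint?

#' Cross-plane ROI overlap analysis
#'
#' ROI areas are the pixels where each max-normalized footprint exceeds
#' `area_threshold`. For every pair of ROIs on *different* planes, the
#' overlap fraction is the shared pixel count divided by the smaller ROI's
#' area (conservative; set `denominator = "first"` for the first-ROI
#' normalization). Pairs whose overlap fraction exceeds `overlap_threshold`
#' are overlapping; overlapping pairs whose temporal correlation exceeds
#' `corr_exclusion` are assumed to be the same bouton (or boutons of one
#' axon) seen twice and are excluded. The overlap ratio is the number of
#' ROIs in the remaining overlapping pairs divided by the number of all
#' other ROIs.
#'
#' @param roisets list of at least two [roi_set]s with identical lateral
#'   geometry, one per plane.
#' @param temporal optional list of `K_p x T` trace matrices per plane used
#'   for the correlation exclusion; defaults to each roi_set's temporal
#'   components.
#' @param area_threshold footprint threshold defining ROI areas.
#' @param overlap_threshold overlap fraction above which a pair counts as
#'   overlapping.
#' @param corr_exclusion temporal-correlation threshold for exclusion.
#' @param denominator `"smaller"` (default) or `"first"`: whose area
#'   normalizes the shared pixel count.
#' @return an object of class `overlap_report`: list with `pairs` (tibble:
#'   `plane_a`, `roi_a`, `plane_b`, `roi_b`, `overlap_px`,
#'   `overlap_fraction`, `temporal_corr`, `overlapping`, `excluded`),
#'   `overlap_ratio`, `n_rois`, `n_overlapping`, `excluded_pairs`.
#' @export
plane_overlap_analysis <- function(roisets, temporal = NULL,
                                   area_threshold = 0.5,
                                   overlap_threshold = 0.5,
                                   corr_exclusion = 0.6,
                                   denominator = c("smaller", "first")) {
  denominator <- match.arg(denominator)
  if (length(roisets) < 2L) stop("need >= 2 planes", call. = FALSE)
  stopifnot(all(vapply(roisets, inherits, TRUE, "roi_set")))
  dims <- roisets[[1]]$dims
  if (!all(vapply(roisets, function(r) identical(r$dims, dims), TRUE))) {
    stop("all planes must share the same lateral geometry", call. = FALSE)
  }
  if (is.null(temporal)) temporal <- lapply(roisets, `[[`, "temporal")

  masks <- lapply(roisets, function(rs) {
    lapply(seq_len(n_rois(rs)), function(k) {
      a <- rs$spatial[, k]
      a / max(a) > area_threshold
    })
  })
  rows <- list()
  for (pa in seq_along(roisets)) {
    for (pb in seq_along(roisets)) {
      if (pb <= pa) next
      for (i in seq_along(masks[[pa]])) {
        for (j in seq_along(masks[[pb]])) {
          ma <- masks[[pa]][[i]]; mb <- masks[[pb]][[j]]
          ov <- sum(ma & mb)
          if (ov == 0L) next
          den <- switch(denominator,
                        smaller = min(sum(ma), sum(mb)),
                        first = sum(ma))
          frac <- ov / den
          ta <- temporal[[pa]][i, ]; tb <- temporal[[pb]][j, ]
          tc <- if (stats::sd(ta) > 0 && stats::sd(tb) > 0)
            stats::cor(ta, tb) else NA_real_
          rows[[length(rows) + 1L]] <- tibble::tibble(
            plane_a = pa, roi_a = i, plane_b = pb, roi_b = j,
            overlap_px = ov, overlap_fraction = frac, temporal_corr = tc
          )
        }
      }
    }
  }
  pairs <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(plane_a = integer(), roi_a = integer(),
                   plane_b = integer(), roi_b = integer(),
                   overlap_px = integer(), overlap_fraction = double(),
                   temporal_corr = double())
  pairs$overlapping <- pairs$overlap_fraction > overlap_threshold
  pairs$excluded <- pairs$overlapping &
    !is.na(pairs$temporal_corr) & pairs$temporal_corr > corr_exclusion

  counted <- pairs[pairs$overlapping & !pairs$excluded, , drop = FALSE]
  ids <- unique(c(paste(counted$plane_a, counted$roi_a),
                  paste(counted$plane_b, counted$roi_b)))
  n_all <- sum(vapply(roisets, n_rois, integer(1)))
  n_over <- length(ids)
  structure(
    list(pairs = pairs,
         excluded_pairs = pairs[pairs$excluded, , drop = FALSE],
         overlap_ratio = n_over / max(n_all - n_over, 1L),
         n_rois = n_all, n_overlapping = n_over),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report> %d ROI(s), %d overlapping (%d pair(s) excluded) | ratio %.3g%%\n",
    x$n_rois, x$n_overlapping, nrow(x$excluded_pairs), 100 * x$overlap_ratio))
  invisible(x)
}
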