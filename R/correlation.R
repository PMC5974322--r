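# Seed-based pixel-wise correlation maps, pairwise ROI correlation structure
# and bouton density along axon-like paths.

#' Down-sample a movie for pixel-wise correlation analysis
#'
#' Non-overlapping spatial mean-binning (`spatial_factor x spatial_factor`
#' blocks) and temporal averaging over `temporal_factor` consecutive frames;
#' trailing partial blocks are dropped. The reference protocol bins 2 x 2
#' pixels and 10 frames, turning 10,000 frames into 1,000 time points.
#'
#' @param movie a [movie_stack()].
#' @param spatial_factor,temporal_factor integer binning factors (`>= 1`).
#' @return the binned [movie_stack()] (pixel size and frame rate rescaled).
#' @export
downsample_for_corr <- function(movie, spatial_factor = 2L,
                                temporal_factor = 10L) {
  stopifnot(inherits(movie, "movie_stack"),
            spatial_factor >= 1, temporal_factor >= 1)
  sf <- as.integer(spatial_factor)
  if (sf > 1L) {
    d <- dim(movie$data)
    h2 <- d[2] %/% sf; w2 <- d[3] %/% sf
    if (h2 < 1L || w2 < 1L) stop("movie smaller than one spatial bin", call. = FALSE)
    dat <- movie$data[, seq_len(h2 * sf), seq_len(w2 * sf), drop = FALSE]
    # average over sf x sf blocks
    dim(dat) <- c(d[1], sf, h2, sf, w2)
    dat <- apply(dat, c(1, 3, 5), mean)
    movie$data <- dat
    movie$um_per_px <- movie$um_per_px * sf
  }
  if (temporal_factor > 1L) {
    movie <- temporal_resample(movie, movie$fps / temporal_factor)
  }
  movie
}

#' Seed-based pixel-wise correlation map
#'
#' Pearson correlation of every pixel's trace with the trace of one chosen
#' seed pixel. The value at the seed is 1 by construction; all values lie
#' in `[-1, 1]`, and the map is invariant under any positive affine
#' transform of the movie intensities.
#'
#' @param movie a (typically down-sampled) [movie_stack()].
#' @param seed_pixel `(row, col)` of the seed.
#' @return an object of class `corr_map`: list with `values` (`H x W`
#'   matrix, NA where a pixel trace is constant), `seed_pixel`, `um_per_px`.
#' @export
seed_correlation_map <- function(movie, seed_pixel) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  r <- seed_pixel[1]; cc <- seed_pixel[2]
  if (r < 1 || r > d[2] || cc < 1 || cc > d[3]) {
    stop("seed pixel outside the field", call. = FALSE)
  }
  Y <- movie_matrix(movie)
  s <- Y[(cc - 1) * d[2] + r, ]
  if (stats::sd(s) == 0) stop("seed trace is constant", call. = FALSE)
  Yc <- Y - rowMeans(Y)
  sc <- s - mean(s)
  denom <- sqrt(rowSums(Yc^2) * sum(sc^2))
  vals <- as.vector(Yc %*% sc) / denom
  vals[denom == 0] <- NA_real_
  structure(
    list(values = matrix(vals, d[2], d[3]),
         seed_pixel = c(r, cc), um_per_px = movie$um_per_px),
    class = "corr_map"
  )
}

#' @export
print.corr_map <- function(x, ...) {
  cat(sprintf("<corr_map> %d x %d px, seed (%d, %d)\n",
              nrow(x$values), ncol(x$values), x$seed_pixel[1], x$seed_pixel[2]))
  invisible(x)
}

#' Pairwise correlation matrix of ROI traces with cluster ordering
#'
#' Pearson correlation matrix of the per-ROI traces, an agglomerative
#' hierarchical clustering on the distance `1 - correlation` (average
#' linkage) whose leaf order groups correlated ROIs contiguously, and a
#' histogram of the upper-triangle coefficients in bins of width 0.02.
#'
#' @param traces a `K x T` matrix of per-ROI traces (rows are ROIs) or a
#'   long tibble with columns `roi`, `frame` and a value column.
#' @param value column name of the trace values when `traces` is a tibble.
#' @param bin_width histogram bin width.
#' @return an object of class `pairwise_corr`: list with `matrix`, `order`
#'   (leaf order), `histogram` (tibble: `mid`, `count`) and `values`
#'   (upper-triangle coefficients).
#' @export
pairwise_correlation <- function(traces, value = "dff", bin_width = 0.02) {
  if (is.data.frame(traces)) {
    traces <- traces %>%
      dplyr::select(dplyr::all_of(c("roi", "frame", value))) %>%
      tidyr::pivot_wider(names_from = "frame", values_from = dplyr::all_of(value)) %>%
      dplyr::arrange(.data$roi) %>%
      dplyr::select(-"roi") %>%
      as.matrix()
  }
  if (nrow(traces) < 2L) stop("need >= 2 ROIs", call. = FALSE)
  cmat <- stats::cor(t(traces))
  dist <- stats::as.dist(1 - cmat)
  hc <- stats::hclust(dist, method = "average")
  ut <- cmat[upper.tri(cmat)]
  breaks <- seq(floor(min(ut) / bin_width) * bin_width,
                ceiling(max(ut) / bin_width) * bin_width + bin_width,
                by = bin_width)
  hcount <- graphics::hist(ut, breaks = breaks, plot = FALSE)
  structure(
    list(matrix = cmat, order = hc$order,
         histogram = tibble::tibble(mid = hcount$mids, count = hcount$counts),
         values = ut, hclust = hc),
    class = "pairwise_corr"
  )
}

#' @export
print.pairwise_corr <- function(x, ...) {
  cat(sprintf("<pairwise_corr> %d ROIs | median pairwise r = %.3f\n",
              nrow(x$matrix), stats::median(x$values)))
  invisible(x)
}

#' Slope of pairwise correlation against pair distance
#'
#' Least-squares slope of the upper-triangle correlation coefficients
#' against the Euclidean distance between the ROI centres of each pair.
#'
#' @param cmat a `K x K` correlation matrix (or a `pairwise_corr`).
#' @param centers_um a `K x 2` matrix / data frame of ROI centre positions
#'   in micrometres.
#' @return list with `slope_per_um`, `intercept` and `n_pairs`.
#' @export
correlation_distance_slope <- function(cmat, centers_um) {
  if (inherits(cmat, "pairwise_corr")) cmat <- cmat$matrix
  centers_um <- as.matrix(centers_um)
  K <- nrow(cmat)
  stopifnot(nrow(centers_um) == K)
  if (K * (K - 1) / 2 < 3) stop("need >= 3 pairs", call. = FALSE)
  ut <- upper.tri(cmat)
  dmat <- as.matrix(stats::dist(centers_um))
  fit <- stats::lm(cmat[ut] ~ dmat[ut])
  list(slope_per_um = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       n_pairs = sum(ut))
}

# Topographic prominence of local maxima of a 1-D profile: the height of a
# peak above the higher of the two minima separating it from greater peaks.
find_peaks_1d <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3L) return(integer())
  is_peak <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  keep <- logical(length(is_peak))
  prom <- numeric(length(is_peak))
  for (i in seq_along(is_peak)) {
    p <- is_peak[i]
    # walk left until a higher point (or the edge); track the minimum
    lmin <- y[p]
    j <- p
    while (j > 1L && y[j - 1L] <= y[p]) {
      j <- j - 1L
      lmin <- min(lmin, y[j])
    }
    if (j == 1L) lmin <- min(lmin, y[1L])
    rmin <- y[p]
    j <- p
    while (j < n && y[j + 1L] <= y[p]) {
      j <- j + 1L
      rmin <- min(rmin, y[j])
    }
    if (j == n) rmin <- min(rmin, y[n])
    prom[i] <- y[p] - max(lmin, rmin)
    keep[i] <- prom[i] >= min_prominence
  }
  is_peak[keep]
}

#' Density of correlation peaks along an axon-like path
#'
#' Samples a correlation map along a polyline path, detects local maxima
#' whose topographic prominence exceeds `min_prominence`, and reports the
#' count per millimetre of path. Invariant under rescaling of the map by a
#' positive constant only up to the prominence threshold, and exactly
#' invariant in the peak positions.
#'
#' @param map a `corr_map` (or plain matrix plus `um_per_px`).
#' @param path_um polyline matrix with columns `x_um`, `y_um`.
#' @param min_prominence minimum prominence, correlation units.
#' @param um_per_px pixel size when `map` is a plain matrix.
#' @param step_um sampling step along the path (defaults to one pixel).
#' @return list with `density_per_mm`, `n_peaks`, `path_length_mm` and
#'   `peaks` (tibble: `arc_um`, `x_um`, `y_um`, `value`).
#' @export
peak_density_along_path <- function(map, path_um, min_prominence = 0.2,
                                    um_per_px = NULL, step_um = NULL) {
  if (inherits(map, "corr_map")) {
    um_per_px <- map$um_per_px
    vals <- map$values
  } else {
    vals <- map
    if (is.null(um_per_px)) stop("`um_per_px` required for a plain matrix",
                                 call. = FALSE)
  }
  path_um <- as.matrix(path_um)
  len_um <- polyline_length(path_um)
  if (len_um <= 0) stop("path length must be > 0", call. = FALSE)
  step_um <- step_um %||% um_per_px
  arcs <- seq(0, len_um, by = step_um)
  pts <- polyline_point(path_um, arcs)
  prof <- bilinear_at(vals, pts[, 2] / um_per_px + 0.5,
                      pts[, 1] / um_per_px + 0.5)
  prof[is.na(prof)] <- 0
  pk <- find_peaks_1d(prof, min_prominence)
  list(
    density_per_mm = boutons_per_mm(length(pk), len_um / 1000),
    n_peaks = length(pk),
    path_length_mm = len_um / 1000,
    peaks = tibble::tibble(arc_um = arcs[pk], x_um = pts[pk, 1],
                           y_um = pts[pk, 2], value = prof[pk]),
    profile = tibble::tibble(arc_um = arcs, value = prof)
  )
}
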