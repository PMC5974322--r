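# PSF metrics: Gaussian FWHM fitting of bead profiles and
# signal-to-background quantification versus depth.

#' Fit a 1-D Gaussian to an intensity profile and report its FWHM
#'
#' Least-squares fit of `offset + amplitude * exp(-(x - center)^2 / (2 sigma^2))`
#' to a sampled intensity profile, initialized from moment estimates. The
#' full width at half maximum is `2 sqrt(2 ln 2) * sigma`. A flat profile or
#' a fit that fails to converge yields an explicit failed-fit result
#' (`converged = FALSE`, NA parameters) rather than a silent NaN.
#'
#' @param coords sample positions (micrometres), at least 5.
#' @param intensities intensity values at `coords`.
#' @return an object of class `psf_fit`: list with `center`, `sigma`, `fwhm`
#'   (micrometres), `amplitude`, `offset`, `residual_rms`, `converged`.
#' @examples
#' x <- seq(-3, 3, by = 0.2)
#' fit <- fit_gaussian_fwhm(x, exp(-x^2 / 2))
#' fit$fwhm  # 2.3548 (sigma = 1)
#' @export
fit_gaussian_fwhm <- function(coords, intensities) {
  if (length(coords) != length(intensities)) {
    stop("`coords` and `intensities` must have equal length", call. = FALSE)
  }
  if (length(coords) < 5L) stop("need at least 5 samples", call. = FALSE)
  failed <- function() {
    structure(list(center = NA_real_, sigma = NA_real_, fwhm = NA_real_,
                   amplitude = NA_real_, offset = NA_real_,
                   residual_rms = NA_real_, converged = FALSE),
              class = "psf_fit")
  }
  rng <- diff(range(intensities))
  if (!is.finite(rng) || rng <= 0) return(failed())
  # moment initialization above the floor
  off0 <- min(intensities)
  wts <- pmax(intensities - off0, 0)
  if (sum(wts) <= 0) return(failed())
  c0 <- sum(coords * wts) / sum(wts)
  s0 <- sqrt(sum((coords - c0)^2 * wts) / sum(wts))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(coords)) / 6
  a0 <- max(intensities) - off0
  model <- function(p) p[1] + p[2] * exp(-(coords - p[3])^2 / (2 * p[4]^2))
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = c(off0, a0, c0, s0),
      fn = function(p) intensities - model(p),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) return(failed())
  p <- fit$par
  if (!all(is.finite(p)) || abs(p[4]) <= 0 || p[2] <= 0) return(failed())
  sig <- abs(p[4])
  structure(
    list(center = p[3], sigma = sig,
         fwhm = sigma_to_fwhm(sig),
         amplitude = p[2], offset = p[1],
         residual_rms = sqrt(mean((intensities - model(p))^2)),
         converged = TRUE),
    class = "psf_fit"
  )
}

#' @export
print.psf_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<psf_fit> fit failed (flat profile or non-convergence)\n")
  } else {
    cat(sprintf("<psf_fit> FWHM %.4g um (sigma %.4g, center %.4g, amp %.4g, offset %.4g)\n",
                x$fwhm, x$sigma, x$center, x$amplitude, x$offset))
  }
  invisible(x)
}

#' Lateral and axial FWHM of a bead in a Z-stack
#'
#' Locates the bead's intensity maximum near `bead_center_px`, refines the
#' centre as the intensity centroid of the brightest 10% of a local cube,
#' extracts the X line through the maximum within the best-focus page and
#' the Z line through the maximum across pages, and fits each with
#' [fit_gaussian_fwhm()]. Z coordinates are pre-scaled by the
#' refractive-index depth correction (`axial_scale`, see
#' [axial_depth_correction()]).
#'
#' @param stack a [movie_stack()] whose first dimension indexes Z pages.
#' @param bead_center_px approximate `(row, col)` pixel position of the bead.
#' @param z_step_um stage step between pages, micrometres.
#' @param axial_scale multiplicative depth correction applied to Z
#'   coordinates (e.g. 1.33 for air into water); 1 for matched indices.
#' @param margin_px bead must sit at least this many pixels / pages inside
#'   the stack.
#' @return list with elements `lateral` and `axial`, each a `psf_fit` (FWHMs
#'   in micrometres).
#' @export
bead_fwhm_3d <- function(stack, bead_center_px, z_step_um, axial_scale = 1,
                         margin_px = 3L) {
  stopifnot(inherits(stack, "movie_stack"))
  d <- dim(stack$data)
  r0 <- round(bead_center_px[1]); c0 <- round(bead_center_px[2])
  # local search window around the nominal centre
  win <- 6L
  rows <- max(1L, r0 - win):min(d[2], r0 + win)
  cols <- max(1L, c0 - win):min(d[3], c0 + win)
  sub <- stack$data[, rows, cols, drop = FALSE]
  mx <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  zi <- mx[1]; ri <- rows[mx[2]]; ci <- cols[mx[3]]
  if (zi <= margin_px || zi > d[1] - margin_px ||
      ri <= margin_px || ri > d[2] - margin_px ||
      ci <= margin_px || ci > d[3] - margin_px) {
    stop("bead too close to the stack edge for a reliable fit", call. = FALSE)
  }
  # centroid of the top 10% of the local cube refines the line placement
  vals <- as.vector(sub)
  thr <- stats::quantile(vals, 0.9, names = FALSE)
  top <- which(sub >= thr, arr.ind = TRUE)
  wts <- sub[top]
  ri <- round(sum(rows[top[, 2]] * wts) / sum(wts))
  ci <- round(sum(cols[top[, 3]] * wts) / sum(wts))
  zi2 <- which.max(stack$data[, ri, ci])

  x_um <- (seq_len(d[3]) - 0.5) * stack$um_per_px
  z_um <- (seq_len(d[1]) - 0.5) * z_step_um * axial_scale
  lateral <- fit_gaussian_fwhm(x_um, stack$data[zi2, ri, ])
  axial <- fit_gaussian_fwhm(z_um, stack$data[, ri, ci])
  list(lateral = lateral, axial = axial)
}

#' Signal-to-background ratio around an in-focus bead
#'
#' The signal is the maximum intensity within a square of side `square_um`
#' centred on the bead; the background is the mean intensity of the same
#' square excluding a central circle of diameter `exclusion_diameter_um`.
#' The ratio is invariant under multiplication of the image by any positive
#' constant.
#'
#' @param image an `H x W` intensity matrix.
#' @param bead_center_px `(row, col)` pixel position of the bead centre.
#' @param um_per_px pixel size, micrometres.
#' @param square_um side of the analysis square (default 30).
#' @param exclusion_diameter_um diameter of the excluded central circle
#'   (default 10).
#' @return the signal-to-background ratio (dimensionless).
#' @export
signal_to_background <- function(image, bead_center_px, um_per_px,
                                 square_um = 30, exclusion_diameter_um = 10) {
  stopifnot(is.matrix(image))
  half <- floor(square_um / um_per_px / 2)
  r0 <- round(bead_center_px[1]); c0 <- round(bead_center_px[2])
  rows <- (r0 - half):(r0 + half)
  cols <- (c0 - half):(c0 + half)
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > nrow(image) || max(cols) > ncol(image)) {
    stop("analysis square does not fit inside the image", call. = FALSE)
  }
  sq <- image[rows, cols]
  rr <- exclusion_diameter_um / um_per_px / 2
  dist2 <- outer(rows - r0, cols - c0, function(a, b) a^2 + b^2)
  bg_px <- sq[dist2 > rr^2]
  bg <- mean(bg_px)
  if (!is.finite(bg) || bg <= 0) {
    stop("background mean is not positive; ratio undefined", call. = FALSE)
  }
  max(sq) / bg
}

#' Signal-to-background depth profile with rank-sum mode comparison
#'
#' Summarizes per-bead signal-to-background ratios by depth and imaging mode
#' (mean and SEM), and compares the two modes at each depth with an exact
#' two-sample Wilcoxon rank-sum test.
#'
#' @param sbr_tbl data frame with columns `depth_um`, `mode` (two levels)
#'   and `sbr`, one row per bead; at least 2 beads per depth and mode.
#' @return a tibble with one row per depth: per-mode `mean` and `sem`
#'   columns, the rank-sum statistic `W` and the exact p-value `p`.
#' @export
sbr_depth_profile <- function(sbr_tbl) {
  stopifnot(all(c("depth_um", "mode", "sbr") %in% names(sbr_tbl)))
  modes <- sort(unique(as.character(sbr_tbl$mode)))
  if (length(modes) != 2L) stop("exactly two modes are required", call. = FALSE)
  sbr_tbl %>%
    dplyr::group_by(.data$depth_um) %>%
    dplyr::group_modify(function(g, key) {
      a <- g$sbr[g$mode == modes[1]]
      b <- g$sbr[g$mode == modes[2]]
      if (length(a) < 2L || length(b) < 2L) {
        stop("need >= 2 beads per depth and mode", call. = FALSE)
      }
      if (stats::sd(c(a, b)) == 0) {
        # identical samples throughout: no evidence of any difference
        W <- length(a) * length(b) / 2
        p <- 1
      } else {
        wt <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE))
        W <- unname(wt$statistic)
        p <- wt$p.value
      }
      tibble::tibble(
        mean_1 = mean(a), sem_1 = stats::sd(a) / sqrt(length(a)),
        mean_2 = mean(b), sem_2 = stats::sd(b) / sqrt(length(b)),
        W = W, p = p
      )
    }) %>%
    dplyr::ungroup() %>%
    dplyr::rename_with(~ sub("_1$", paste0("_", modes[1]), .x)) %>%
    dplyr::rename_with(~ sub("_2$", paste0("_", modes[2]), .x))
}
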