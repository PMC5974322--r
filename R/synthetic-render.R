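# Rendering ground-truth scenes into calcium movies and bead phantoms.

# Peak-normalized 2-D Gaussian footprints of the boutons on the pixel grid.
# Returns a dense npx x n_boutons matrix (column-major H x W pixel order).
bouton_footprints <- function(boutons, field_um, um_per_px, psf_fwhm_um) {
  w_px <- max(1L, round(field_um[1] / um_per_px))
  h_px <- max(1L, round(field_um[2] / um_per_px))
  sigma_px <- fwhm_to_sigma(psf_fwhm_um) / um_per_px
  single_px <- FALSE
  if (psf_fwhm_um / um_per_px < 1 && nrow(boutons) > 0L) {
    warning("PSF narrower than one pixel; boutons rendered as single pixels",
            call. = FALSE)
    single_px <- TRUE
  }
  nb <- nrow(boutons)
  A <- matrix(0, h_px * w_px, max(nb, 0L))
  if (nb == 0L) return(list(A = A, h = h_px, w = w_px))
  half <- max(1L, ceiling(4 * sigma_px))
  for (b in seq_len(nb)) {
    # pixel-centre coordinates: pixel i covers ((i-1)..i) * um_per_px
    cx <- boutons$x_um[b] / um_per_px + 0.5
    cy <- boutons$y_um[b] / um_per_px + 0.5
    if (single_px) {
      r <- pmin(pmax(round(cy), 1L), h_px)
      cc <- pmin(pmax(round(cx), 1L), w_px)
      A[(cc - 1L) * h_px + r, b] <- 1
      next
    }
    rows <- max(1L, floor(cy - half)):min(h_px, ceiling(cy + half))
    cols <- max(1L, floor(cx - half)):min(w_px, ceiling(cx + half))
    gy <- exp(-(rows - cy)^2 / (2 * sigma_px^2))
    gx <- exp(-(cols - cx)^2 / (2 * sigma_px^2))
    patch <- gy %o% gx
    idx <- as.vector(outer(rows, (cols - 1L) * h_px, `+`))
    A[idx, b] <- A[idx, b] + as.vector(patch)
  }
  list(A = A, h = h_px, w = w_px)
}

#' Render a ground-truth scene into a noisy calcium movie
#'
#' Each frame is the sum of a constant baseline, one Gaussian spot per bouton
#' (lateral FWHM `psf_fwhm_um`, peak amplitude `bouton_amp` scaled by that
#' bouton's calcium trace), and a spatially smooth neuropil field modulated
#' by the low-pass-filtered population activity. Pixel noise is then *added*
#' as independent gamma draws with shape `gamma_shape` and scale
#' `sqrt(nr * m / gamma_shape)` where `m` is that pixel's noise-free temporal
#' mean — so the added noise has variance exactly `nr * m`, the
#' mean-proportional noise law summarized by the noise ratio NR. `nr = 0`
#' adds nothing.
#'
#' @param truth a [generate_scene()] ground truth.
#' @param um_per_px pixel size of the rendered movie (micrometres).
#' @param psf_fwhm_um lateral FWHM of the optical blur (micrometres).
#' @param neuropil_amp peak amplitude of the neuropil background (intensity).
#' @param baseline constant baseline intensity (arbitrary units, `> 0`).
#' @param nr noise ratio: slope of added-noise variance against the
#'   noise-free pixel mean (`>= 0`).
#' @param gamma_shape gamma shape parameter `k` of the pixel noise.
#' @param seed integer RNG seed for the noise and neuropil field.
#' @param bouton_amp peak fluorescence of a unit calcium transient, one value
#'   or one per bouton.
#' @param bouton_scale optional extra per-bouton amplitude factor (used for
#'   axial weighting in multi-plane rendering).
#' @return a [movie_stack()] with extra elements `baseline_map` (H x W
#'   noise-free temporal mean, strictly positive) and `nr_used`.
#' @examples
#' tr <- generate_scene(c(60, 60), n_axons = 1, duration_s = 5, fps = 10, seed = 1)
#' mov <- render_movie(tr, um_per_px = 1.05, nr = 1, seed = 2)
#' @export
render_movie <- function(truth, um_per_px = 1.05, psf_fwhm_um = 1.7,
                         neuropil_amp = 0, baseline = 100, nr = 1,
                         gamma_shape = 2.57, seed = 1, bouton_amp = 40,
                         bouton_scale = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  assert_scalar_pos(psf_fwhm_um, "psf_fwhm_um")
  assert_scalar_pos(baseline, "baseline")
  assert_scalar_pos(nr, "nr", zero_ok = TRUE)
  assert_scalar_pos(gamma_shape, "gamma_shape")
  fp <- bouton_footprints(truth$boutons, truth$field_um, um_per_px, psf_fwhm_um)
  npx <- fp$h * fp$w
  n_t <- truth$n_frames
  nb <- nrow(truth$boutons)

  amp <- rep_len(bouton_amp, max(nb, 1L))
  if (!is.null(bouton_scale)) amp <- amp * rep_len(bouton_scale, max(nb, 1L))

  with_seed(seed, {
    M <- matrix(baseline, npx, n_t)
    pop <- numeric(n_t)
    if (nb > 0L) {
      C <- matrix(0, nb, n_t)
      for (b in seq_len(nb)) {
        C[b, ] <- amp[b] * spikes_to_calcium(
          truth$spikes[b, ], fps = truth$fps,
          rise_s = truth$kernel$rise_s, decay_s = truth$kernel$decay_s
        )
      }
      M <- M + fp$A %*% C
      pop_raw <- colMeans(C / pmax(amp, .Machine$double.eps))
      if (max(pop_raw) > 0) pop <- pop_raw / max(pop_raw)
    }
    if (neuropil_amp > 0) {
      # smooth random field, mean 1, blurred over ~20 um
      f <- matrix(stats::runif(npx), fp$h, fp$w)
      f <- gauss_blur_matrix(f, 20 / um_per_px)
      f <- f / mean(f)
      # low-pass the population activity over ~1 s
      win <- max(1L, round(truth$fps))
      lp <- stats::filter(pop, rep(1 / win, win), sides = 2)
      lp[is.na(lp)] <- 0
      M <- M + as.vector(f) %o% (neuropil_amp * as.numeric(lp))
    }
    m_px <- rowMeans(M)
    if (nr > 0) {
      theta <- sqrt(nr * m_px / gamma_shape)
      M <- M + matrix(stats::rgamma(npx * n_t, shape = gamma_shape,
                                    scale = theta), npx, n_t)
    }
    mov <- movie_stack(matrix_to_movie(M, fp$h, fp$w),
                       fps = truth$fps, um_per_px = um_per_px)
    mov$baseline_map <- matrix(m_px, fp$h, fp$w)
    mov$nr_used <- nr
    mov
  })
}

#' Render a 3-D ground-truth scene at several imaging planes
#'
#' Each bouton contributes to each plane with a weight given by a Gaussian
#' axial profile of FWHM `axial_fwhm_um` evaluated at the distance between
#' the bouton depth and the plane depth. Planes are rendered with independent
#' noise streams derived from `seed`. The default plane spacing in multiplane
#' protocols for this preparation is 8 micrometres.
#'
#' @param truth a [generate_scene()] ground truth (use `thickness_um > 0`
#'   for a genuinely 3-D scene).
#' @param plane_depths_um numeric vector of at least two plane depths.
#' @param axial_fwhm_um axial FWHM of the point-spread function.
#' @param ... further arguments passed to [render_movie()].
#' @param seed integer RNG seed.
#' @return a list of [movie_stack()]s, one per plane, with `depth_um` set.
#' @export
render_multiplane <- function(truth, plane_depths_um, axial_fwhm_um = 8.49,
                              seed = 1, ...) {
  stopifnot(inherits(truth, "ground_truth"))
  if (length(plane_depths_um) < 2L) {
    stop("at least two plane depths are required", call. = FALSE)
  }
  assert_scalar_pos(axial_fwhm_um, "axial_fwhm_um")
  sz <- fwhm_to_sigma(axial_fwhm_um)
  lapply(seq_along(plane_depths_um), function(i) {
    d <- plane_depths_um[i]
    w <- exp(-(truth$boutons$z_um - d)^2 / (2 * sz^2))
    mov <- render_movie(truth, bouton_scale = w,
                        seed = seed + i - 1L, ...)
    mov$depth_um <- d
    mov
  })
}

#' Axial plane weights of boutons
#'
#' Gaussian axial weight of each bouton at each plane depth; the weighting
#' used by [render_multiplane()], exposed for direct inspection.
#'
#' @param z_um bouton depths (micrometres).
#' @param plane_depths_um plane depths (micrometres).
#' @param axial_fwhm_um axial FWHM of the point-spread function.
#' @return matrix `length(z_um) x length(plane_depths_um)` of weights in
#'   `(0, 1]`.
#' @export
plane_weights <- function(z_um, plane_depths_um, axial_fwhm_um) {
  sz <- fwhm_to_sigma(axial_fwhm_um)
  outer(z_um, plane_depths_um, function(z, d) exp(-(z - d)^2 / (2 * sz^2)))
}

#' Generate a fluorescent-bead phantom Z-stack
#'
#' Renders beads embedded in a scattering medium as Gaussian spots with a
#' depth-dependent blur, imaged at a series of focal depths. Excitation and
#' collection losses attenuate intensity as `exp(-depth / attenuation)`. In
#' `widefield` mode the defocused light of out-of-focus beads is spread over
#' the field as a background proportional to the out-of-plane bead flux; in
#' `confocal` mode the pinholes reject all but a fraction
#' `pinhole_rejection` of that background.
#'
#' @param bead_positions_um matrix or data frame with columns `x_um`, `y_um`,
#'   `z_um` (bead centres, micrometres).
#' @param bead_diameter_um physical bead diameter.
#' @param depths_um focal depths of the stack pages (micrometres).
#' @param field_um field size `c(width_x, height_y)`.
#' @param um_per_px pixel size.
#' @param attenuation_length_um depth attenuation length (`> 0`).
#' @param lateral_fwhm_um,axial_fwhm_um optical PSF FWHMs at depth 0.
#' @param blur_growth additional lateral Gaussian sigma per micrometre of
#'   focal depth (scattering-induced blur growth).
#' @param mode `"confocal"` or `"widefield"`.
#' @param pinhole_rejection fraction of defocused background passed by the
#'   pinholes in confocal mode.
#' @param brightness nominal peak intensity of an in-focus bead.
#' @return a [movie_stack()] whose first dimension indexes stack pages, with
#'   extra element `depths_um`.
#' @export
generate_bead_phantom <- function(bead_positions_um, bead_diameter_um = 2,
                                  depths_um, field_um = c(100, 100),
                                  um_per_px = 1.05,
                                  attenuation_length_um = 150,
                                  lateral_fwhm_um = 0.68,
                                  axial_fwhm_um = 8.49,
                                  blur_growth = 0.01,
                                  mode = c("confocal", "widefield"),
                                  pinhole_rejection = 0.05,
                                  brightness = 1000) {
  mode <- match.arg(mode)
  assert_scalar_pos(attenuation_length_um, "attenuation_length_um")
  beads <- as.data.frame(bead_positions_um)
  stopifnot(all(c("x_um", "y_um", "z_um") %in% names(beads)))
  w_px <- max(1L, round(field_um[1] / um_per_px))
  h_px <- max(1L, round(field_um[2] / um_per_px))
  # bead size adds to the optical blur in quadrature (sphere ~ sigma d/4)
  s_lat0 <- sqrt(fwhm_to_sigma(lateral_fwhm_um)^2 + (bead_diameter_um / 4)^2)
  s_ax <- sqrt(fwhm_to_sigma(axial_fwhm_um)^2 + (bead_diameter_um / 4)^2)
  bg_coef <- if (mode == "widefield") 1 else pinhole_rejection

  pages <- array(0, c(length(depths_um), h_px, w_px))
  for (p in seq_along(depths_um)) {
    d <- depths_um[p]
    att <- exp(-d / attenuation_length_um)
    s_lat <- s_lat0 + blur_growth * d
    img <- matrix(0, h_px, w_px)
    out_flux <- 0
    for (b in seq_len(nrow(beads))) {
      wz <- exp(-(beads$z_um[b] - d)^2 / (2 * s_ax^2))
      amp <- brightness * att * wz
      out_flux <- out_flux + brightness * att * (1 - wz) *
        2 * pi * (s_lat / um_per_px)^2
      if (amp < brightness * 1e-6) next
      cx <- beads$x_um[b] / um_per_px + 0.5
      cy <- beads$y_um[b] / um_per_px + 0.5
      sp <- s_lat / um_per_px
      half <- max(1L, ceiling(4 * sp))
      rows <- max(1L, floor(cy - half)):min(h_px, ceiling(cy + half))
      cols <- max(1L, floor(cx - half)):min(w_px, ceiling(cx + half))
      img[rows, cols] <- img[rows, cols] +
        amp * exp(-(rows - cy)^2 / (2 * sp^2)) %o%
              exp(-(cols - cx)^2 / (2 * sp^2))
    }
    pages[p, , ] <- img + bg_coef * out_flux / (h_px * w_px)
  }
  stk <- movie_stack(pages, fps = 1, um_per_px = um_per_px)
  stk$depths_um <- depths_um
  stk$mode <- mode
  stk
}
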