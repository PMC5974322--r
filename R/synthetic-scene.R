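# Ground-truth scene generation: axonal arbors, boutons, spike trains.

# Evaluate an expression with a temporary RNG seed, restoring the caller's
# RNG state afterwards. Every public generator routes its randomness through
# this single stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Generate a ground-truth synthetic scene of axonal arbors and boutons
#'
#' Builds the ground truth that the synthetic movies are rendered from:
#' smoothed random-walk axonal arbors crossing a rectangular field, boutons
#' placed along each arbor as a 1-D Poisson process, a Poisson parent spike
#' train per arbor, and per-bouton spike trains obtained by independent
#' thinning of the parent train with a per-bouton release probability drawn
#' uniformly in `[0.7, 1]`. Boutons of one arbor therefore share most — but
#' not all — of their events, which reproduces the sub-unity activity
#' correlations of boutons on a common axon.
#'
#' Defaults mirror anatomy and activity of layer-1 thalamocortical arbors:
#' about 110 boutons per mm of axon and tens of calcium events per minute.
#'
#' @param field_um field size in micrometres, `c(width_x, height_y)`.
#' @param n_axons number of axonal arbors (`>= 1`).
#' @param bouton_density_per_mm boutons per mm of arbor length (`>= 0`).
#' @param event_rate_per_min parent-train event rate(s), events per minute:
#'   a single rate shared by all arbors, or one rate per arbor (recycled to
#'   `n_axons`) to emulate the natural heterogeneity of activity rates
#'   across axons (tens of events per minute).
#' @param duration_s scene duration in seconds.
#' @param fps frame rate of the spike trains (frames per second).
#' @param seed integer RNG seed (mandatory; same seed, same scene).
#' @param thickness_um axial extent: each arbor is assigned a constant depth
#'   drawn uniformly in `[0, thickness_um]` (0 gives a flat 2-D scene).
#' @param step_um random-walk step length of the arbor generator.
#'
#' @return An object of class `ground_truth`: a list with `arbors` (list of
#'   polyline matrices, columns `x_um`, `y_um`), `arbor_z_um`, `boutons`
#'   (tibble: `bouton`, `axon`, `x_um`, `y_um`, `z_um`, `release_prob`),
#'   `parent_spikes` (`n_axons x T` 0/1 matrix), `spikes`
#'   (`n_boutons x T` 0/1 matrix), `kernel` (rise/decay time constants,
#'   unit amplitude), `field_um`, `fps`, `duration_s` and `seed`.
#' @examples
#' tr <- generate_scene(c(200, 200), n_axons = 2, seed = 1, duration_s = 10)
#' nrow(tr$boutons)
#' @export
generate_scene <- function(field_um, n_axons = 3,
                           bouton_density_per_mm = 110,
                           event_rate_per_min = 40,
                           duration_s = 60, fps = 60, seed,
                           thickness_um = 0, step_um = 2) {
  if (length(field_um) != 2L || any(!is.finite(field_um)) || any(field_um <= 0)) {
    stop("`field_um` must be two positive lengths", call. = FALSE)
  }
  if (min(field_um) < 5 * step_um) {
    stop("field too small to contain an arbor (need >= ", 5 * step_um,
         " um on each side)", call. = FALSE)
  }
  stopifnot(n_axons >= 1)
  assert_scalar_pos(bouton_density_per_mm, "bouton_density_per_mm", zero_ok = TRUE)
  if (any(!is.finite(event_rate_per_min)) || any(event_rate_per_min < 0)) {
    stop("`event_rate_per_min` must be nonnegative", call. = FALSE)
  }
  rates <- rep_len(event_rate_per_min, n_axons)
  assert_scalar_pos(duration_s, "duration_s")
  assert_scalar_pos(fps, "fps")
  p_event <- rates / 60 / fps
  if (any(p_event > 1)) stop("event rate exceeds one event per frame", call. = FALSE)
  n_frames <- max(1L, round(duration_s * fps))

  with_seed(seed, {
    arbors <- lapply(seq_len(n_axons), function(i) random_arbor(field_um, step_um))
    arbor_z <- if (thickness_um > 0) stats::runif(n_axons, 0, thickness_um)
               else rep(0, n_axons)

    bouton_list <- lapply(seq_len(n_axons), function(i) {
      pl <- arbors[[i]]
      len_mm <- polyline_length(pl) / 1000
      n_b <- stats::rpois(1L, bouton_density_per_mm * len_mm)
      if (n_b == 0L) {
        return(tibble::tibble(axon = integer(), x_um = double(),
                              y_um = double(), z_um = double(),
                              release_prob = double()))
      }
      pos <- polyline_point(pl, sort(stats::runif(n_b, 0, polyline_length(pl))))
      tibble::tibble(
        axon = i, x_um = pos[, 1], y_um = pos[, 2], z_um = arbor_z[i],
        release_prob = stats::runif(n_b, 0.7, 1.0)
      )
    })
    boutons <- dplyr::bind_rows(bouton_list)
    boutons <- dplyr::mutate(boutons, bouton = dplyr::row_number(),
                             .before = 1L)

    parent_spikes <- t(vapply(seq_len(n_axons), function(i) {
      stats::rbinom(n_frames, 1L, p_event[i])
    }, integer(n_frames)))
    spikes <- matrix(0L, nrow(boutons), n_frames)
    if (nrow(boutons) > 0L) {
      for (b in seq_len(nrow(boutons))) {
        parent <- parent_spikes[boutons$axon[b], ]
        keep <- stats::rbinom(n_frames, 1L, boutons$release_prob[b])
        spikes[b, ] <- parent * keep
      }
    }

    structure(
      list(
        arbors = arbors, arbor_z_um = arbor_z, boutons = boutons,
        parent_spikes = parent_spikes, spikes = spikes,
        kernel = list(rise_s = 0.18, decay_s = 1.8, amplitude = 1),
        field_um = as.numeric(field_um), fps = fps,
        duration_s = duration_s, n_frames = n_frames, seed = seed
      ),
      class = "ground_truth"
    )
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d arbor(s), %d bouton(s) in %g x %g um | %g s at %g fps (seed %d)\n",
    length(x$arbors), nrow(x$boutons), x$field_um[1], x$field_um[2],
    x$duration_s, x$fps, x$seed
  ))
  invisible(x)
}

# A smoothed random walk entering at one field edge and walking until it
# leaves the field; heading increments are capped so curvature stays gentle,
# then the polyline is refined with a cubic spline.
random_arbor <- function(field_um, step_um = 2,
                         heading_sd = 0.05, heading_cap = 0.12) {
  w <- field_um[1]; h <- field_um[2]
  edge <- sample.int(4L, 1L)
  start <- switch(edge,
    c(stats::runif(1, 0, w), 0),            # bottom
    c(stats::runif(1, 0, w), h),            # top
    c(0, stats::runif(1, 0, h)),            # left
    c(w, stats::runif(1, 0, h))             # right
  )
  inward <- switch(edge, pi / 2, -pi / 2, 0, pi)
  heading <- inward + stats::runif(1, -0.6, 0.6)
  max_steps <- ceiling(4 * sqrt(w^2 + h^2) / step_um)
  pts <- matrix(NA_real_, max_steps + 1L, 2L)
  pts[1L, ] <- start
  n <- 1L
  repeat {
    heading <- heading + max(-heading_cap, min(heading_cap,
                                               stats::rnorm(1, 0, heading_sd)))
    nxt <- pts[n, ] + step_um * c(cos(heading), sin(heading))
    n <- n + 1L
    pts[n, ] <- nxt
    if (nxt[1] < 0 || nxt[1] > w || nxt[2] < 0 || nxt[2] > h) break
    if (n > max_steps) break
  }
  pts <- pts[seq_len(n), , drop = FALSE]
  # clip terminal point onto the field boundary
  pts[n, ] <- pmin(pmax(pts[n, ], c(0, 0)), c(w, h))
  if (n >= 4L) {
    s <- seq_len(n)
    ss <- seq(1, n, length.out = 3L * n)
    pts <- cbind(stats::spline(s, pts[, 1], xout = ss)$y,
                 stats::spline(s, pts[, 2], xout = ss)$y)
    pts[, 1] <- pmin(pmax(pts[, 1], 0), w)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), h)
  }
  colnames(pts) <- c("x_um", "y_um")
  pts
}

# Total arc length of a polyline (same units as its coordinates).
polyline_length <- function(pl) {
  if (nrow(pl) < 2L) return(0)
  sum(sqrt(rowSums(diff(pl)^2)))
}

# Points at given arc-length positions along a polyline.
polyline_point <- function(pl, s) {
  seg <- sqrt(rowSums(diff(pl)^2))
  cs <- c(0, cumsum(seg))
  s <- pmin(pmax(s, 0), cs[length(cs)])
  idx <- findInterval(s, cs, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(pl) - 1L)
  frac <- ifelse(seg[idx] > 0, (s - cs[idx]) / seg[idx], 0)
  pl[idx, , drop = FALSE] + (pl[idx + 1L, , drop = FALSE] - pl[idx, , drop = FALSE]) * frac
}

#' Convolve a spike train with a calcium-indicator kernel
#'
#' The indicator response is a difference of exponentials,
#' `h(t) = exp(-t/decay) - exp(-t/rise)`, normalized to unit peak, so a
#' single event produces a transient that rises over `rise_s` seconds and
#' decays over `decay_s` seconds with peak amplitude exactly 1. The trace is
#' the linear superposition of one kernel per event and is everywhere
#' nonnegative.
#'
#' @param spike_train numeric vector of event counts/amplitudes per frame.
#' @param fps frame rate of the train (frames per second).
#' @param rise_s,decay_s kernel time constants in seconds; `decay_s` must
#'   exceed `rise_s`, both positive. Defaults are typical slow-indicator
#'   (GCaMP6s-like) constants.
#' @return numeric fluorescence trace of the same length as `spike_train`.
#' @examples
#' tr <- spikes_to_calcium(c(0, 1, rep(0, 58)), fps = 10)
#' max(tr)  # 1 (unit peak)
#' @export
spikes_to_calcium <- function(spike_train, fps, rise_s = 0.18, decay_s = 1.8) {
  assert_scalar_pos(fps, "fps")
  assert_scalar_pos(rise_s, "rise_s")
  assert_scalar_pos(decay_s, "decay_s")
  if (decay_s <= rise_s) stop("`decay_s` must exceed `rise_s`", call. = FALSE)
  n <- length(spike_train)
  if (n == 0L) return(numeric(0))
  if (all(spike_train == 0)) return(numeric(n))
  t <- seq(0, by = 1 / fps, length.out = max(2L, ceiling(8 * decay_s * fps)))
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h <- h / max(h)
  out <- numeric(n + length(h) - 1L)
  idx <- which(spike_train != 0)
  for (i in idx) {
    j <- i:(i + length(h) - 1L)
    out[j] <- out[j] + spike_train[i] * h
  }
  out[seq_len(n)]
}
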