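# ROI extraction: a simplified constrained nonnegative matrix factorization.
#
# The movie (pixels x time matrix Y) is decomposed as
#   Y ~ A C + b f'
# with nonnegative per-ROI spatial footprints A (columns a_i supported on a
# small patch), nonnegative temporal components C (rows c_i), and a rank-1
# nonnegative background b f'. Components are seeded greedily at maxima of
# the temporal-activity energy of a high-pass-filtered movie, then refined
# by hierarchical alternating least squares (HALS); each HALS coordinate
# update is an exact projected least-squares step, so the residual norm is
# non-increasing across alternations. Spike events are inferred from each
# temporal component by nonnegative deconvolution under an AR(1) model whose
# coefficient is the lag-1/lag-0 autocovariance ratio, thresholded at three
# times the estimated noise SD.

#' Set of ROIs extracted from a movie
#'
#' Container returned by [extract_rois()]: max-normalized spatial footprints,
#' temporal components, inferred event series, the rank-1 background and the
#' footprint-maximum centres. Footprints are stored as a `npx x K` matrix in
#' column-major `H x W` pixel order; [roi_footprint()] returns one as an
#' `H x W` image.
#'
#' @param rois a `roi_set`.
#' @param i ROI index.
#' @name roi_set
NULL

new_roi_set <- function(spatial, temporal, events, centers,
                        background_spatial, background_temporal,
                        dims, fps, um_per_px, residual_history = numeric()) {
  structure(
    list(spatial = spatial, temporal = temporal, events = events,
         centers = centers, background_spatial = background_spatial,
         background_temporal = background_temporal, dims = dims,
         fps = fps, um_per_px = um_per_px,
         residual_history = residual_history),
    class = "roi_set"
  )
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROI(s) in %d x %d px | %d frame(s) at %g fps\n",
              n_rois(x), x$dims[1], x$dims[2], ncol(x$temporal), x$fps))
  invisible(x)
}

#' @rdname roi_set
#' @export
n_rois <- function(rois) ncol(rois$spatial)

#' @rdname roi_set
#' @export
roi_footprint <- function(rois, i) {
  matrix(rois$spatial[, i], rois$dims[1], rois$dims[2])
}

# Robust frame-to-frame noise SD of a trace.
trace_noise_sd <- function(x) {
  if (length(x) < 3L) return(0)
  stats::mad(diff(x)) / sqrt(2)
}

#' Extract ROIs and their activity from a movie
#'
#' Runs the simplified constrained nonnegative matrix factorization described
#' above on a registered, filtered (and typically 6 Hz-resampled) movie.
#' Components whose peak denoised amplitude is below `min_snr` times their
#' estimated noise SD are discarded; components closer than `merge_dist_px`
#' with temporal correlation above `merge_corr` are merged.
#'
#' @param movie a [movie_stack()].
#' @param max_components maximum number of components to seed.
#' @param min_snr signal-to-noise acceptance threshold.
#' @param seed integer RNG seed (the factorization itself is deterministic;
#'   the seed fixes any stochastic tie-breaking).
#' @param patch_radius_px half-size of the square patch supporting each
#'   footprint.
#' @param n_iter number of outer HALS alternations.
#' @param event_sd_mult event threshold in units of the noise SD.
#' @param merge_dist_px,merge_corr merge rule (centre distance, temporal
#'   correlation).
#' @return a [roi_set]; zero components (not an error) when the movie has no
#'   temporal variance. `residual_history` records the residual norm after
#'   each alternation.
#' @export
extract_rois <- function(movie, max_components = 50, min_snr = 4, seed = 1,
                         patch_radius_px = 4L, n_iter = 10L,
                         event_sd_mult = 3, merge_dist_px = 2,
                         merge_corr = 0.8) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  h <- d[2]; w <- d[3]; n_t <- d[1]; npx <- h * w
  Y <- movie_matrix(movie)

  empty <- function() new_roi_set(
    spatial = matrix(0, npx, 0), temporal = matrix(0, 0, n_t),
    events = matrix(0, 0, n_t),
    centers = tibble::tibble(roi = integer(), row = integer(), col = integer()),
    background_spatial = matrix(rowMeans(Y), h, w),
    background_temporal = rep(1, n_t),
    dims = c(h, w), fps = movie$fps, um_per_px = movie$um_per_px
  )
  if (n_t < 2L) return(empty())

  px_mean <- rowMeans(Y)
  Z <- Y - px_mean
  if (max(abs(Z)) == 0) return(empty())
  # temporal smoothing (3-frame boxcar) before computing activity energy
  if (n_t >= 3L) {
    Zs <- (Z[, c(1, 1:(n_t - 1))] + Z + Z[, c(2:n_t, n_t)]) / 3
  } else Zs <- Z
  noise_px <- apply(Z[sample.int(npx, min(npx, 2000L)), , drop = FALSE], 1,
                    trace_noise_sd)
  sd0 <- stats::median(noise_px)
  energy <- rowSums(pmax(Zs, 0)^2)
  # energy of pure noise at a pixel: ~ T/2 * sd^2 (smoothed noise var ~ sd^2/3)
  stop_energy <- 4 * (n_t / 2) * (sd0^2 / 3 + 1e-12)

  patch_of <- function(p) {
    r <- ((p - 1L) %% h) + 1L
    cc <- ((p - 1L) %/% h) + 1L
    rows <- max(1L, r - patch_radius_px):min(h, r + patch_radius_px)
    cols <- max(1L, cc - patch_radius_px):min(w, cc + patch_radius_px)
    as.vector(outer(rows, (cols - 1L) * h, `+`))
  }

  # greedy seeding: repeatedly take the pixel with maximal positive temporal
  # energy, fit a nonnegative rank-1 component on its patch, subtract
  greedy_seeds <- function(Zw, energy, max_n) {
    seeds <- list()
    for (k in seq_len(max_n)) {
      p <- which.max(energy)
      if (energy[p] <= stop_energy) break
      sup <- patch_of(p)
      Zp <- Zw[sup, , drop = FALSE]
      cvec <- pmax(Zp[match(p, sup), ], 0)
      avec <- NULL
      for (it in 1:5) {
        avec <- pmax(Zp %*% cvec, 0) / max(sum(cvec^2), 1e-12)
        cvec <- pmax(crossprod(avec, Zp), 0)[1, ] / max(sum(avec^2), 1e-12)
      }
      if (max(avec) <= 0 || max(cvec) <= 0) {
        energy[p] <- 0
        next
      }
      seeds[[length(seeds) + 1L]] <- list(sup = sup, a = as.vector(avec),
                                          c = cvec)
      Zp_new <- Zp - avec %*% t(cvec)
      Zw[sup, ] <- Zp_new
      energy[sup] <- rowSums(pmax(Zp_new, 0)^2)
    }
    seeds
  }
  seeds <- greedy_seeds(Zs, energy, max_components)
  K <- length(seeds)
  if (K == 0L) return(empty())

  A <- matrix(0, npx, K)
  C <- matrix(0, K, n_t)
  sup_list <- vector("list", K)
  for (k in seq_len(K)) {
    A[seeds[[k]]$sup, k] <- seeds[[k]]$a
    C[k, ] <- seeds[[k]]$c
    sup_list[[k]] <- seeds[[k]]$sup
  }
  b <- pmax(px_mean, 0)
  f <- rep(1, n_t)

  R <- Y - A %*% C - b %*% t(f)
  res_hist <- numeric(0)
  hals_sweeps <- function(n_sweeps) for (it in seq_len(n_sweeps)) {
    for (k in seq_len(K)) {
      sup <- sup_list[[k]]
      ak <- A[sup, k]
      na <- sum(ak^2)
      if (na > 0) {
        ck_new <- pmax(C[k, ] + crossprod(ak, R[sup, , drop = FALSE])[1, ] / na, 0)
        dk <- C[k, ] - ck_new
        if (any(dk != 0)) {
          R[sup, ] <<- R[sup, , drop = FALSE] + ak %*% t(dk)
          C[k, ] <<- ck_new
        }
      }
      ck <- C[k, ]
      nc <- sum(ck^2)
      if (nc > 0) {
        ak_new <- pmax(A[sup, k] + (R[sup, , drop = FALSE] %*% ck)[, 1] / nc, 0)
        da <- A[sup, k] - ak_new
        if (any(da != 0)) {
          R[sup, ] <<- R[sup, , drop = FALSE] + da %*% t(ck)
          A[sup, k] <<- ak_new
        }
      }
    }
    nb <- sum(b^2)
    if (nb > 0) {
      f_new <- pmax(f + crossprod(b, R)[1, ] / nb, 0)
      df_ <- f - f_new
      if (any(df_ != 0)) {
        R <<- R + b %*% t(df_)
        f <<- f_new
      }
    }
    nf <- sum(f^2)
    if (nf > 0) {
      b_new <- pmax(b + (R %*% f)[, 1] / nf, 0)
      db <- b - b_new
      if (any(db != 0)) {
        R <<- R + db %*% t(f)
        b <<- b_new
      }
    }
    res_hist <<- c(res_hist, sqrt(sum(R^2)))
  }
  hals_sweeps(n_iter)

  # a second seeding pass on the residual picks up components whose shared
  # signal was absorbed by an earlier neighbour (close same-axon boutons)
  if (K < max_components) {
    Rs <- if (n_t >= 3L) {
      (R[, c(1, 1:(n_t - 1))] + R + R[, c(2:n_t, n_t)]) / 3
    } else R
    energy2 <- rowSums(pmax(Rs, 0)^2)
    # do not re-seed on top of an existing component: mask pixels within the
    # merge distance of current centres (unconverged residue, not a bouton)
    cur <- apply(A, 2, which.max)
    cur_r <- ((cur - 1L) %% h) + 1L
    cur_c <- ((cur - 1L) %/% h) + 1L
    px_r <- ((seq_len(npx) - 1L) %% h) + 1L
    px_c <- ((seq_len(npx) - 1L) %/% h) + 1L
    for (j in seq_along(cur)) {
      near <- (px_r - cur_r[j])^2 + (px_c - cur_c[j])^2 <= merge_dist_px^2
      energy2[near] <- 0
    }
    extra <- greedy_seeds(Rs, energy2, max_components - K)
    added <- FALSE
    for (s in extra) {
      # accept only if the seed strictly reduces the raw residual, so the
      # recorded residual norm stays non-increasing
      Rp <- R[s$sup, , drop = FALSE]
      Rp_new <- Rp - s$a %*% t(s$c)
      if (sum(Rp_new^2) >= sum(Rp^2)) next
      A <- cbind(A, 0)
      A[s$sup, K + 1L] <- s$a
      C <- rbind(C, s$c)
      sup_list[[K + 1L]] <- s$sup
      R[s$sup, ] <- Rp_new
      K <- K + 1L
      added <- TRUE
    }
    if (added) hals_sweeps(max(3L, n_iter %/% 2L))
  }

  # events by AR(1) nonnegative deconvolution, thresholded at
  # event_sd_mult x noise SD; SNR filter on the denoised trace
  keep <- logical(K)
  events <- matrix(0, K, n_t)
  denoised <- matrix(0, K, n_t)
  for (k in seq_len(K)) {
    ck <- C[k, ]
    if (max(ck) <= 0) next
    cc <- ck - mean(ck)
    g <- sum(cc[-1] * cc[-n_t]) / max(sum(cc^2), 1e-12)
    g <- max(0, min(0.95, g))
    s <- pmax(ck - g * c(0, ck[-n_t]), 0)
    s[1] <- 0
    sd_c <- trace_noise_sd(ck)
    # noise-scaled threshold with a relative floor so that noise-free traces
    # do not count every tiny deconvolution residue as an event
    thr <- max(event_sd_mult * sd_c * sqrt(1 + g^2), 0.05 * max(ck))
    s[s < thr] <- 0
    # a rise split across two frames leaves a small residue bin right after
    # the onset bin; fold it back in (a genuine second spike has comparable
    # amplitude and is kept)
    idx <- which(s > 0)
    for (i in idx) {
      if (i < n_t && s[i] > 0 && s[i + 1L] > 0 && s[i + 1L] < 0.5 * s[i]) {
        s[i] <- s[i] + s[i + 1L]
        s[i + 1L] <- 0
      }
    }
    events[k, ] <- s
    dn <- stats::filter(s, g, method = "recursive")
    denoised[k, ] <- as.numeric(dn)
    snr <- if (sd_c > 0) max(denoised[k, ]) / sd_c else Inf
    keep[k] <- snr >= min_snr && max(A[, k]) > 0
  }
  # drop residue components far below the strongest one
  pk <- apply(denoised, 1, max)
  keep <- keep & pk >= 0.05 * max(pk)
  A <- A[, keep, drop = FALSE]
  C <- denoised[keep, , drop = FALSE]
  events <- events[keep, , drop = FALSE]
  K <- sum(keep)
  if (K == 0L) return(empty())

  centers_of <- function(A) {
    idx <- apply(A, 2, which.max)
    tibble::tibble(roi = seq_len(ncol(A)),
                   row = ((idx - 1L) %% h) + 1L,
                   col = ((idx - 1L) %/% h) + 1L)
  }

  # merge near-duplicate components
  repeat {
    ctr <- centers_of(A)
    merged <- FALSE
    if (K >= 2L) {
      for (i in seq_len(K - 1L)) {
        for (j in (i + 1L):K) {
          dist <- sqrt((ctr$row[i] - ctr$row[j])^2 + (ctr$col[i] - ctr$col[j])^2)
          if (dist < merge_dist_px &&
              stats::sd(C[i, ]) > 0 && stats::sd(C[j, ]) > 0 &&
              stats::cor(C[i, ], C[j, ]) > merge_corr) {
            A[, i] <- A[, i] + A[, j]
            C[i, ] <- (C[i, ] + C[j, ]) / 2
            events[i, ] <- events[i, ] + events[j, ]
            A <- A[, -j, drop = FALSE]
            C <- C[-j, , drop = FALSE]
            events <- events[-j, , drop = FALSE]
            K <- K - 1L
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }

  # max-normalize footprints, folding the scale into the temporal components
  mx <- apply(A, 2, max)
  A <- sweep(A, 2, mx, "/")
  C <- sweep(C, 1, mx, "*")
  events <- sweep(events, 1, mx, "*")

  new_roi_set(
    spatial = A, temporal = C, events = events, centers = centers_of(A),
    background_spatial = matrix(b, h, w), background_temporal = f,
    dims = c(h, w), fps = movie$fps, um_per_px = movie$um_per_px,
    residual_history = res_hist
  )
}

#' Match extracted ROIs to ground-truth bouton positions
#'
#' Nearest-centre matching within `max_dist_px`: a bouton counts as
#' recovered when some ROI centre lies within `max_dist_px` of it, and an
#' ROI counts as genuine when some bouton lies within `max_dist_px` of its
#' centre. The matching is deliberately not one-to-one: boutons closer
#' together than the optical footprint are rendered as a single spot, so a
#' single ROI legitimately accounts for all of them. `matches` additionally
#' reports a one-to-one greedy pairing (closest pairs first) for trace-level
#' comparisons.
#'
#' @param rois a [roi_set].
#' @param truth a [generate_scene()] ground truth.
#' @param max_dist_px maximum centre distance for a match.
#' @return list with `matches` (tibble `roi`, `bouton`, `dist_px`), `recall`
#'   (fraction of boutons with an ROI within range), `precision` (fraction
#'   of ROIs with a bouton within range) and `mean_center_error_px` (mean
#'   bouton-to-nearest-ROI distance over recovered boutons).
#' @export
match_rois_to_truth <- function(rois, truth, max_dist_px = 3) {
  stopifnot(inherits(rois, "roi_set"), inherits(truth, "ground_truth"))
  nb <- nrow(truth$boutons)
  nr <- n_rois(rois)
  if (nb == 0L || nr == 0L) {
    return(list(matches = tibble::tibble(roi = integer(), bouton = integer(),
                                         dist_px = double()),
                recall = if (nb == 0L) NA_real_ else 0,
                precision = if (nr == 0L) NA_real_ else 0,
                mean_center_error_px = NA_real_))
  }
  up <- rois$um_per_px
  tr <- truth$boutons$y_um / up + 0.5
  tc <- truth$boutons$x_um / up + 0.5
  dmat <- outer(rois$centers$row, tr, `-`)^2 + outer(rois$centers$col, tc, `-`)^2
  dmat <- sqrt(dmat)
  pairs <- which(dmat <= max_dist_px, arr.ind = TRUE)
  if (nrow(pairs) > 0L) pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
  used_r <- logical(nr); used_b <- logical(nb)
  out <- list()
  for (idx in seq_len(nrow(pairs))) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    if (used_r[i] || used_b[j]) next
    used_r[i] <- TRUE; used_b[j] <- TRUE
    out[[length(out) + 1L]] <- tibble::tibble(roi = i, bouton = j,
                                              dist_px = dmat[i, j])
  }
  matches <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(roi = integer(), bouton = integer(), dist_px = double())
  nearest_to_bouton <- apply(dmat, 2, min)
  nearest_to_roi <- apply(dmat, 1, min)
  recovered <- nearest_to_bouton <= max_dist_px
  list(
    matches = matches,
    recall = mean(recovered),
    precision = mean(nearest_to_roi <= max_dist_px),
    mean_center_error_px = if (any(recovered))
      mean(nearest_to_bouton[recovered]) else NA_real_
  )
}
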