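# Shared fixture builders. Everything is generated in code at test time;
# scenes are kept small so the default run stays fast.

# A small rendered scene with ground truth attached.
small_scene_movie <- function(seed = 11, px = 96, um_per_px = 1.05,
                              n_axons = 2, density = 40, rate = 40,
                              duration_s = 60, fps = 6, nr = 0.5,
                              neuropil_amp = 5, bouton_amp = 40) {
  field <- px * um_per_px
  truth <- generate_scene(c(field, field), n_axons = n_axons,
                          bouton_density_per_mm = density,
                          event_rate_per_min = rate,
                          duration_s = duration_s, fps = fps, seed = seed)
  movie <- render_movie(truth, um_per_px = um_per_px, psf_fwhm_um = 1.7,
                        neuropil_amp = neuropil_amp, baseline = 100,
                        nr = nr, seed = seed + 1, bouton_amp = bouton_amp)
  list(truth = truth, movie = movie)
}

# A constant-baseline movie (no boutons) for noise-moment checks.
flat_movie <- function(n_frames = 2000, px = 8, baseline = 100, fps = 10) {
  movie_stack(array(baseline, c(n_frames, px, px)), fps = fps, um_per_px = 1)
}

# Independent oracle: two-sample KS statistic by brute-force CDF enumeration
# over the union of sample points.
ks_stat_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), numeric(1))))
}

# Map bouton positions (um) to pixel coordinates of a rendered movie.
bouton_px <- function(truth, um_per_px) {
  cbind(row = truth$boutons$y_um / um_per_px + 0.5,
        col = truth$boutons$x_um / um_per_px + 0.5)
}
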