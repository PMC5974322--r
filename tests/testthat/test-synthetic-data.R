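test_that("scene generation is deterministic and respects the bouton process", {
  tr1 <- generate_scene(c(1000, 1000), n_axons = 3, bouton_density_per_mm = 110,
                        event_rate_per_min = 40, duration_s = 10, fps = 60,
                        seed = 1)
  tr2 <- generate_scene(c(1000, 1000), n_axons = 3, bouton_density_per_mm = 110,
                        event_rate_per_min = 40, duration_s = 10, fps = 60,
                        seed = 1)
  expect_identical(tr1, tr2)

  # bouton count is Poisson with rate density x total arbor length:
  # check the count against a 99.9% Poisson interval
  len_mm <- sum(vapply(tr1$arbors, boutonscope:::polyline_length, 1)) / 1000
  lam <- 110 * len_mm
  expect_gte(nrow(tr1$boutons), qpois(5e-4, lam))
  expect_lte(nrow(tr1$boutons), qpois(1 - 5e-4, lam))

  # every bouton lies on (within 0.5 um of) its parent polyline
  for (b in seq_len(min(nrow(tr1$boutons), 50))) {
    pl <- tr1$arbors[[tr1$boutons$axon[b]]]
    d <- sqrt((pl[, 1] - tr1$boutons$x_um[b])^2 +
              (pl[, 2] - tr1$boutons$y_um[b])^2)
    expect_lt(min(d), 0.5)
  }

  # bouton events are a thinned subset of the parent train
  for (b in seq_len(min(nrow(tr1$boutons), 50))) {
    parent <- tr1$parent_spikes[tr1$boutons$axon[b], ]
    expect_true(all(tr1$spikes[b, ] <= parent))
  }
})

test_that("zero bouton density and tiny fields behave as specified", {
  tr <- generate_scene(c(100, 100), n_axons = 1, bouton_density_per_mm = 0,
                       duration_s = 5, fps = 10, seed = 3)
  expect_equal(nrow(tr$boutons), 0L)
  expect_error(generate_scene(c(4, 4), n_axons = 1, seed = 1),
               "too small")
})

test_that("calcium kernel has unit peak, linearity and nonnegativity", {
  expect_equal(spikes_to_calcium(numeric(50), fps = 10), numeric(50))
  one <- spikes_to_calcium(c(0, 1, rep(0, 120)), fps = 10)
  expect_equal(max(one), 1)
  expect_gt(which.max(one), 2)     # peak strictly after the event
  expect_true(all(one >= 0))
  # two well-separated events superpose linearly
  s1 <- c(1, rep(0, 199)); s2 <- c(rep(0, 100), 1, rep(0, 99))
  expect_equal(spikes_to_calcium(s1 + s2, fps = 10),
               spikes_to_calcium(s1, fps = 10) + spikes_to_calcium(s2, fps = 10))
  expect_error(spikes_to_calcium(c(1, 0), fps = 10, rise_s = 2, decay_s = 1),
               "decay")
})

test_that("rendering an empty noiseless scene gives exactly the baseline", {
  tr <- generate_scene(c(20, 20), n_axons = 1, bouton_density_per_mm = 0,
                       duration_s = 2, fps = 5, seed = 4)
  mov <- render_movie(tr, um_per_px = 2, neuropil_amp = 0, baseline = 80,
                      nr = 0, seed = 5)
  expect_true(all(mov$data == 80))
  expect_true(all(mov$baseline_map > 0))
})

test_that("rendered movies are deterministic and place boutons correctly", {
  sc <- small_scene_movie(seed = 7, px = 48, duration_s = 10, nr = 1)
  sc2 <- small_scene_movie(seed = 7, px = 48, duration_s = 10, nr = 1)
  expect_identical(sc$movie$data, sc2$movie$data)

  # single bouton, no noise: frame maximum lands on the bouton +/- 1 px
  tr <- generate_scene(c(50, 50), n_axons = 1, bouton_density_per_mm = 25,
                       event_rate_per_min = 60, duration_s = 20, fps = 10,
                       seed = 19)
  tr$boutons <- tr$boutons[1, , drop = FALSE]
  tr$spikes <- tr$spikes[1, , drop = FALSE]
  mov <- render_movie(tr, um_per_px = 1, neuropil_amp = 0, nr = 0, seed = 1)
  pk_frame <- which.max(apply(mov$data, 1, max))
  fr <- mov$data[pk_frame, , ]
  pos <- which(fr == max(fr), arr.ind = TRUE)[1, ]
  px <- bouton_px(tr, 1)
  expect_lte(abs(pos[1] - px[1, "row"]), 1)
  expect_lte(abs(pos[2] - px[1, "col"]), 1)
})

test_that("added gamma noise follows the mean-proportional variance law", {
  tr <- generate_scene(c(16, 16), n_axons = 1, bouton_density_per_mm = 0,
                       duration_s = 40, fps = 100, seed = 2)
  mov <- render_movie(tr, um_per_px = 2, baseline = 100, nr = 2, seed = 3)
  Y <- apply(mov$data, c(2, 3), var)
  expect_lt(abs(mean(Y) / (2 * 100) - 1), 0.1)
})

test_that("multi-plane rendering weights boutons by axial distance", {
  w <- plane_weights(c(0, 4), c(0, 8), axial_fwhm_um = 3.2)
  expect_lt(w[1, 2] / w[1, 1], 1e-3)     # on-plane bouton invisible 8 um away
  expect_equal(w[2, 1], w[2, 2])          # midway bouton weighted equally
  tr <- generate_scene(c(40, 40), n_axons = 1, bouton_density_per_mm = 50,
                       duration_s = 5, fps = 10, seed = 9, thickness_um = 8)
  expect_error(render_multiplane(tr, plane_depths_um = 4), "two plane")
  planes <- render_multiplane(tr, plane_depths_um = c(0, 8),
                              axial_fwhm_um = 3.2, um_per_px = 2, nr = 0,
                              seed = 1)
  expect_length(planes, 2)
  expect_equal(planes[[2]]$depth_um, 8)
})

test_that("bead phantoms follow attenuation and pinhole-rejection physics", {
  beads <- data.frame(x_um = c(50.5, 20.5), y_um = c(50.5, 80.5),
                      z_um = c(0, 150))
  conf <- generate_bead_phantom(beads, depths_um = c(0, 150, 210),
                                field_um = c(101, 101), um_per_px = 1,
                                attenuation_length_um = 150,
                                mode = "confocal")
  wf <- generate_bead_phantom(beads, depths_um = c(0, 150, 210),
                              field_um = c(101, 101), um_per_px = 1,
                              attenuation_length_um = 150,
                              mode = "widefield")
  # in-focus bead at depth 0: peak equals nominal brightness
  expect_equal(max(conf$data[1, , ]), 1000, tolerance = 1e-2)
  # bead at depth = attenuation length: peak 1/e of nominal (background off)
  pk <- max(conf$data[2, , ]) - median(conf$data[2, , ])
  expect_equal(pk, 1000 / exp(1), tolerance = 1e-2)
  # widefield background >= confocal background at every depth
  for (p in 1:3) {
    expect_gte(min(wf$data[p, , ]), min(conf$data[p, , ]))
  }
})
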