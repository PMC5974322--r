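test_that("downsampling bins space and time by block means", {
  arr <- array(runif(8 * 6 * 6), c(8, 6, 6))
  mov <- movie_stack(arr, fps = 60, um_per_px = 1)
  expect_identical(downsample_for_corr(mov, 1, 1)$data, arr)
  # 4x4 checkerboard of 0/2 binned 2x2 becomes uniform 1
  chk <- matrix(c(0, 2, 2, 0), 2, 2)[rep(1:2, 2), rep(1:2, 2)]
  mc <- movie_stack(array(rep(chk, each = 3), c(3, 4, 4)), fps = 60,
                    um_per_px = 1)
  ds <- downsample_for_corr(mc, 2, 1)
  expect_true(all(ds$data == 1))
  expect_equal(ds$um_per_px, 2)
  # 10 000 frames averaged over 10 -> 1000 time points
  long <- movie_stack(array(1, c(10000, 2, 2)), fps = 60, um_per_px = 1)
  expect_equal(n_frames(downsample_for_corr(long, 1, 10)), 1000)
})

test_that("seed correlation maps are Pearson maps with value 1 at the seed", {
  set.seed(12)
  arr <- array(runif(40 * 5 * 5), c(40, 5, 5))
  arr[, 4, 4] <- 10 - arr[, 2, 2]          # anti-correlated pixel
  mov <- movie_stack(arr, fps = 1, um_per_px = 1)
  cm <- seed_correlation_map(mov, c(2, 2))
  expect_equal(cm$values[2, 2], 1)
  expect_equal(cm$values[4, 4], -1)
  expect_true(all(abs(cm$values) <= 1 + 1e-12, na.rm = TRUE))
  # invariant under positive affine transforms of the movie
  mov2 <- mov; mov2$data <- 3 * mov$data + 7
  expect_equal(seed_correlation_map(mov2, c(2, 2))$values, cm$values)
  expect_error(seed_correlation_map(mov, c(9, 9)), "outside")
  flat <- movie_stack(array(2, c(10, 3, 3)), 1, 1)
  expect_error(seed_correlation_map(flat, c(2, 2)), "constant")
})

test_that("same-axon boutons light up in the seed map, others do not", {
  tr <- generate_scene(c(140, 140), n_axons = 2, bouton_density_per_mm = 80,
                       event_rate_per_min = 40, duration_s = 200, fps = 6,
                       seed = 33)
  mov <- render_movie(tr, um_per_px = 1.05, psf_fwhm_um = 1.7,
                      neuropil_amp = 3, baseline = 100, nr = 0.5, seed = 32,
                      bouton_amp = 40)
  b <- tr$boutons
  expect_gte(min(table(b$axon)), 3)
  b1 <- b[b$axon == 1, ][1, ]
  up <- 1.05
  cm <- seed_correlation_map(mov, c(round(b1$y_um / up + 0.5),
                                    round(b1$x_um / up + 0.5)))
  same <- b[b$axon == 1, ][-1, ]
  oth <- b[b$axon == 2, ]
  vs <- boutonscope:::bilinear_at(cm$values, same$y_um / up + 0.5,
                                  same$x_um / up + 0.5)
  vo <- boutonscope:::bilinear_at(cm$values, oth$y_um / up + 0.5,
                                  oth$x_um / up + 0.5)
  expect_true(all(vs > 0.5))
  expect_true(all(vo < 0.3))
})

test_that("pairwise correlation structure and clustering group axons", {
  t1 <- sin(seq(0, 20, length.out = 500))
  pc1 <- pairwise_correlation(rbind(t1, t1))
  expect_true(all(abs(pc1$matrix - 1) < 1e-12))
  # block-structured set: leaf order keeps each axon contiguous
  tr <- generate_scene(c(140, 140), n_axons = 2, bouton_density_per_mm = 80,
                       event_rate_per_min = 40, duration_s = 200, fps = 6,
                       seed = 33)
  C <- t(sapply(seq_len(nrow(tr$boutons)),
                function(b) spikes_to_calcium(tr$spikes[b, ], fps = 6)))
  set.seed(3)
  C <- C + matrix(rnorm(length(C), 0, 0.05), nrow(C))
  pc <- pairwise_correlation(C, bin_width = 0.02)
  ax <- tr$boutons$axon[pc$order]
  expect_equal(sum(diff(ax) != 0), 1)      # one block boundary
  # independent noise traces decorrelate
  set.seed(4)
  noise <- matrix(rnorm(12 * 1000), 12, 1000)
  pcn <- pairwise_correlation(noise)
  expect_lt(median(abs(pcn$values)), 0.1)
  expect_error(pairwise_correlation(noise[1, , drop = FALSE]), ">= 2")
})

test_that("correlation-distance slope is an exact regression", {
  set.seed(5)
  centers <- cbind(runif(12, 0, 1000), runif(12, 0, 1000))
  dmat <- as.matrix(dist(centers))
  cmat <- 0.5 - 1e-4 * dmat
  diag(cmat) <- 1
  sl <- correlation_distance_slope(cmat, centers)
  expect_equal(sl$slope_per_um, -1e-4)
  # distance-independent correlations: slope ~ 0
  cmat0 <- matrix(0.3, 12, 12); diag(cmat0) <- 1
  expect_equal(correlation_distance_slope(cmat0, centers)$slope_per_um, 0,
               tolerance = 1e-12)
  expect_error(correlation_distance_slope(cmat[1:2, 1:2], centers[1:2, ]),
               "3 pairs")
})

test_that("peak density along a path counts prominent bumps per mm", {
  map <- matrix(0, 101, 1001)
  xs <- seq_len(1001) - 0.5
  for (cx in seq(50, 950, by = 100)) {
    map[51, ] <- map[51, ] + 0.8 * exp(-(xs - cx)^2 / (2 * 3^2))
  }
  path <- cbind(x_um = seq(0, 1000, by = 5), y_um = 50)
  pd <- peak_density_along_path(map, path, min_prominence = 0.2, um_per_px = 1)
  expect_equal(pd$n_peaks, 10)
  expect_equal(pd$density_per_mm, 10, tolerance = 0.01)
  # flat profile: no peaks
  pd0 <- peak_density_along_path(matrix(0.2, 101, 1001), path,
                                 min_prominence = 0.2, um_per_px = 1)
  expect_equal(pd0$n_peaks, 0)
  # peak positions invariant under rescaling of the map
  pd2 <- peak_density_along_path(2 * map, path, min_prominence = 0.4,
                                 um_per_px = 1)
  expect_equal(pd2$peaks$arc_um, pd$peaks$arc_um)
  expect_error(peak_density_along_path(map, path[1, , drop = FALSE],
                                       um_per_px = 1), "> 0")
})

test_that("hand arithmetic: 144 peaks over 2.10 mm is 68.6 per mm", {
  expect_equal(round(boutons_per_mm(144, 2.10), 1), 68.6)
})
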