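test_that("rigid registration recovers injected integer jitter", {
  set.seed(4)
  base <- matrix(0, 32, 32)
  base[10:14, 20:24] <- 50
  base <- base + matrix(runif(32 * 32), 32, 32)
  jit <- rbind(c(0, 0), c(2, -1), c(-2, 2), c(1, 1), c(0, -2))
  arr <- array(0, c(5, 32, 32))
  for (t in 1:5) arr[t, , ] <- boutonscope:::shift_matrix(base, jit[t, 1], jit[t, 2])
  reg <- register_rigid(movie_stack(arr, fps = 10, um_per_px = 1),
                        reference = 1)
  expect_lt(max(abs(as.matrix(reg$shifts[, c("dy_px", "dx_px")]) - jit)), 0.5)
  # corrected frames match the reference frame away from the borders
  expect_equal(reg$movie$data[3, 5:28, 5:28], arr[1, 5:28, 5:28])
})

test_that("registration of static or single-frame movies is the identity", {
  arr <- array(rep(matrix(1:16, 4, 4), each = 3), c(3, 4, 4))
  reg <- register_rigid(movie_stack(arr, 10, 1))
  expect_true(all(reg$shifts$dy_px == 0) && all(reg$shifts$dx_px == 0))
  one <- movie_stack(array(runif(16), c(1, 4, 4)), 10, 1)
  expect_identical(register_rigid(one)$movie$data, one$data)
  zz <- array(0, c(2, 8, 8)); zz[1, 4, 4] <- 1
  expect_warning(register_rigid(movie_stack(zz, 10, 1), reference = 1),
                 "all-zero")
})

test_that("spatial filtering is mass-conserving and sigma = 0 is identity", {
  arr <- array(runif(3 * 16 * 16), c(3, 16, 16))
  mov <- movie_stack(arr, fps = 10, um_per_px = 0.5)
  expect_identical(spatial_filter(mov, 0)$data, arr)
  # delta image spreads into a Gaussian of matching sigma
  dl <- array(0, c(1, 31, 31)); dl[1, 16, 16] <- 1
  sm <- spatial_filter(movie_stack(dl, 1, 1), sigma_um = 2)
  prof <- sm$data[1, 16, ]
  fit <- fit_gaussian_fwhm(seq_len(31), prof)
  expect_equal(fit$sigma, 2, tolerance = 0.02)
  # total intensity of an interior spot is conserved
  expect_equal(sum(sm$data), 1, tolerance = 1e-6)
})

test_that("temporal resampling block-averages and drops partial blocks", {
  mov <- movie_stack(array(1, c(216, 2, 2)), fps = 60, um_per_px = 1)
  out <- temporal_resample(mov, 6)
  expect_equal(n_frames(out), 21)          # blocks of 10, trailing 6 dropped
  expect_equal(out$fps, 6)
  expect_true(all(out$data == 1))          # constant stays constant
  alt <- movie_stack(array(rep(c(0, 2), 5), c(10, 1, 1)), fps = 10, um_per_px = 1)
  expect_true(all(temporal_resample(alt, 5)$data == 1))
  expect_error(temporal_resample(mov, 120), "exceed")
})

test_that("roi_fluorescence is the support-averaged weighted movie", {
  arr <- array(0, c(2, 3, 3))
  arr[1, , ] <- matrix(1:9, 3, 3); arr[2, , ] <- matrix(9:1, 3, 3)
  mov <- movie_stack(arr, fps = 1, um_per_px = 1)
  # one-hot footprint: trace equals the movie at that pixel
  A <- matrix(0, 9, 1); A[5, 1] <- 1
  rs <- boutonscope:::new_roi_set(
    spatial = A, temporal = matrix(0, 1, 2), events = matrix(0, 1, 2),
    centers = tibble::tibble(roi = 1L, row = 2L, col = 2L),
    background_spatial = matrix(0, 3, 3), background_temporal = rep(0, 2),
    dims = c(3, 3), fps = 1, um_per_px = 1)
  tr <- roi_fluorescence(mov, rs)
  expect_equal(tr$f_roi, c(arr[1, 2, 2], arr[2, 2, 2]))
  # linearity in the movie
  mov2 <- mov; mov2$data <- 2 * mov$data
  expect_equal(roi_fluorescence(mov2, rs)$f_roi, 2 * tr$f_roi)
  # uniform footprint a over 4 pixels with values (0, 2, 4, 6) -> 3 a
  a <- 0.7
  A2 <- matrix(0, 9, 1); A2[c(1, 2, 3, 4), 1] <- a
  rs2 <- rs; rs2$spatial <- A2
  arr3 <- array(0, c(1, 3, 3)); arr3[1, 1:3, 1] <- c(0, 2, 4); arr3[1, 1, 2] <- 6
  expect_equal(roi_fluorescence(movie_stack(arr3, 1, 1), rs2)$f_roi, 3 * a)
})

test_that("percentile baseline behaves in whole and sliding modes", {
  expect_equal(baseline_f(rep(5, 100), fps = 10, mode = "whole"), rep(5, 100))
  # 99% of the trace at 100 with brief transients to 200: whole-mode 8th
  # percentile stays at the floor
  tr <- rep(100, 1000); tr[sample(1000, 10)] <- 200
  expect_equal(baseline_f(tr, fps = 10, mode = "whole")[1], 100)
  # sliding baseline of a monotone ramp is non-decreasing
  bl <- baseline_f(seq(0, 99), fps = 1, mode = "sliding", window_s = 10)
  expect_true(all(diff(bl) >= 0))
  # agrees with a direct quantile at an interior point
  t0 <- 50
  expect_equal(bl[t0], unname(quantile(seq(0, 99)[(t0 - 10):(t0 + 10)], 0.08)))
})

test_that("dF/F is exact and rejects nonpositive baselines by index", {
  expect_equal(dff(c(1, 2, 3), c(1, 2, 3)), c(0, 0, 0))
  expect_equal(dff(rep(200, 4), rep(100, 4)), rep(1, 4))
  expect_equal(dff(120, 100), 0.2)
  expect_error(dff(c(1, 1), c(1, 0)), "index 2")
})

test_that("ROI area metrics match the analytic half-max radius", {
  # Gaussian footprint sigma = 2 px on a 0.21 um grid:
  # half-max radius sigma*sqrt(2 ln 2) -> diameter 2*sigma*sqrt(2 ln 2)*0.21
  h <- 25; sig <- 2
  g <- exp(-(outer((1:h) - 13, (1:h) - 13, function(a, b) a^2 + b^2)) /
             (2 * sig^2))
  rs <- boutonscope:::new_roi_set(
    spatial = matrix(as.vector(g), ncol = 1),
    temporal = matrix(0, 1, 2), events = matrix(0, 1, 2),
    centers = tibble::tibble(roi = 1L, row = 13L, col = 13L),
    background_spatial = matrix(0, h, h), background_temporal = rep(0, 2),
    dims = c(h, h), fps = 1, um_per_px = 0.21)
  met <- roi_area_metrics(rs)
  expect_equal(met$diameter_um, 2 * sig * sqrt(2 * log(2)) * 0.21,
               tolerance = 0.21 / 2)
  # single-pixel footprint
  rs1 <- rs; rs1$spatial <- matrix(c(1, rep(0, h * h - 1)), ncol = 1)
  rs1$centers <- tibble::tibble(roi = 1L, row = 1L, col = 1L)
  met1 <- roi_area_metrics(rs1)
  expect_equal(met1$area_um2, 0.21^2)
  expect_true(met1$edge_excluded)        # at the corner, inside the 4 um margin
  # scaling the footprint leaves the area unchanged
  rs10 <- rs; rs10$spatial <- 10 * rs$spatial
  expect_equal(roi_area_metrics(rs10)$area_um2, met$area_um2)
})

test_that("average ROI image reproduces identical and mirrored footprints", {
  h <- 15
  g <- exp(-(outer((1:h) - 8, (1:h) - 8, function(a, b) a^2 + 2 * b^2)) / 8)
  A <- cbind(as.vector(g), as.vector(g))
  rs <- boutonscope:::new_roi_set(
    spatial = A, temporal = matrix(0, 2, 2), events = matrix(0, 2, 2),
    centers = tibble::tibble(roi = 1:2, row = c(8L, 8L), col = c(8L, 8L)),
    background_spatial = matrix(0, h, h), background_temporal = rep(0, 2),
    dims = c(h, h), fps = 1, um_per_px = 1)
  avg <- average_roi_image(rs, half_width_px = 5L)
  expect_equal(avg$image, g[3:13, 3:13] / max(g))
  # mirror-image pair averages to a symmetric image
  A2 <- cbind(as.vector(g), as.vector(g[, h:1]))
  rs$spatial <- A2
  avg2 <- average_roi_image(rs, half_width_px = 5L)
  expect_equal(avg2$image, avg2$image[, 11:1])
})

test_that("spike-event rate arithmetic is exact", {
  ev <- rep(c(1, 0), c(327, 273))
  expect_equal(spike_event_rate(ev, duration_s = 600), 32.7)
  expect_equal(spike_event_rate(numeric(0), duration_s = 60), 0)
  expect_equal(spike_event_rate(c(0.1, 0.4, 0), 60, threshold = 0.2), 1)
})
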