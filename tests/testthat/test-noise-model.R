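test_that("signal normalization divides by the variance of pixel means", {
  # 3x3 toy, hand-computable
  mi <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 9), 3, 3)
  arr <- array(0, c(2, 3, 3))
  arr[1, , ] <- mi; arr[2, , ] <- mi          # temporal mean = mi
  mov <- movie_stack(arr, fps = 1, um_per_px = 1)
  nm <- normalize_signals(mov, vessel_mask = matrix(FALSE, 3, 3))
  expect_equal(nm$normalizer, var(as.vector(mi)))
  expect_equal(nm$data[1, , ], mi / var(as.vector(mi)))
  # masking the brightest column changes the normalizer accordingly
  mask <- matrix(FALSE, 3, 3); mask[, 3] <- TRUE
  nm2 <- normalize_signals(mov, vessel_mask = mask)
  expect_equal(nm2$normalizer, var(as.vector(mi[, 1:2])))
  # degenerate: identical pixels
  flat <- movie_stack(array(5, c(2, 3, 3)), 1, 1)
  expect_error(normalize_signals(flat, matrix(FALSE, 3, 3)), "zero")
})

test_that("gamma fitting recovers shape and scale from samples", {
  set.seed(8)
  x <- rgamma(21600, shape = 2.35, scale = 2.87)
  fit <- fit_pixel_gamma(x)
  expect_gt(fit$k, 2.2); expect_lt(fit$k, 2.5)
  expect_gt(fit$theta, 2.7); expect_lt(fit$theta, 3.05)
  # exponential special case, k = 1
  y <- rexp(5000, rate = 0.5)
  fit1 <- fit_pixel_gamma(y)
  expect_equal(fit1$k, 1, tolerance = 0.1)
  expect_error(fit_pixel_gamma(c(x[1:200], -1)), "support")
  expect_error(fit_pixel_gamma(rep(2, 200)), "degenerate")
  expect_error(fit_pixel_gamma(x[1:50]), "100")
})

test_that("NR estimation is an exact regression slope", {
  st <- tibble::tibble(mean = seq(1, 20), variance = 3.71 * seq(1, 20))
  expect_equal(estimate_nr(st)$nr, 3.71)
  expect_equal(estimate_nr(st)$intercept, 0)
  st2 <- tibble::tibble(mean = seq(1, 20), variance = rep(4, 20))
  expect_equal(estimate_nr(st2)$nr, 0)
  expect_error(estimate_nr(tibble::tibble(mean = 1:5, variance = 1:5)),
               "10 pixels")
  expect_equal(glance(estimate_nr(st))$nr, 3.71)
})

test_that("injected noise obeys the gamma moment identities", {
  mov <- flat_movie(n_frames = 10000, px = 8, baseline = 10)
  expect_identical(inject_noise(mov, 0)$data, mov$data)
  noisy <- inject_noise(mov, nr = 2, k = 2.57, seed = 6)
  added <- noisy$data - 10
  # variance k theta^2 = nr * m = 20; mean k theta = sqrt(k nr m)
  v <- apply(added, c(2, 3), var)
  expect_lt(abs(mean(v) / 20 - 1), 0.1)
  expect_lt(abs(mean(added) / sqrt(2.57 * 2 * 10) - 1), 0.05)
  expect_true(all(added >= 0))
  # determinism
  expect_identical(inject_noise(mov, 2, seed = 6)$data, noisy$data)
})

test_that("NR is recovered from injected pixels regressed on true means", {
  base <- seq(5, 50, length.out = 100)
  arr <- array(rep(base, each = 2000), c(2000, 10, 10))
  mov <- movie_stack(arr, fps = 10, um_per_px = 1)
  noisy <- inject_noise(mov, nr = 2, seed = 7)
  v <- apply(noisy$data, c(2, 3), var)
  fit <- estimate_nr(tibble::tibble(mean = base, variance = as.vector(v)))
  expect_lt(abs(fit$nr / 2 - 1), 0.1)
  # the paper-faithful observed-mean protocol through fit_noise_model
  fit2 <- fit_noise_model(noisy, n_pixels = 100, seed = 1)
  expect_s3_class(fit2, "noise_model_fit")
  expect_gt(fit2$nr, 0)
})

test_that("degradation ratios are exactly 1 at NR = 0 and error on empty input", {
  sc <- small_scene_movie(seed = 51, px = 64, duration_s = 40, nr = 0,
                          density = 60, neuropil_amp = 0)
  ds <- degradation_study(sc$movie, nr_list = numeric(0), max_components = 15)
  r0 <- ds$ratios[ds$ratios$nr == 0, ]
  expect_equal(r0$roi_ratio, 1)
  expect_equal(r0$event_ratio, 1)
  expect_equal(r0$event_corr, 1)
  flat <- movie_stack(array(5, c(30, 16, 16)), fps = 6, um_per_px = 1)
  expect_error(degradation_study(flat, nr_list = 1), "no ROIs")
})

test_that("tiny injected noise barely perturbs the extraction", {
  sc <- small_scene_movie(seed = 53, px = 64, duration_s = 40, nr = 0,
                          density = 60, neuropil_amp = 0)
  ds <- degradation_study(sc$movie, nr_list = 0.01, max_components = 15,
                          seed = 2)
  r <- ds$ratios[ds$ratios$nr == 0.01, ]
  expect_gte(r$roi_ratio, 0.95)
  expect_gte(r$event_ratio, 0.95)
  expect_gte(r$event_corr, 0.95)
})

test_that("KS comparison equals the brute-force CDF supremum", {
  a <- tibble::tibble(area = c(1, 2, 3))
  expect_equal(robust_roi_comparison(a, a)$D, 0)
  b <- tibble::tibble(area = c(11, 12, 13))
  expect_equal(robust_roi_comparison(a, b)$D, 1)
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  d <- robust_roi_comparison(tibble::tibble(v = x), tibble::tibble(v = y))$D
  expect_equal(d, ks_stat_brute(x, y))
  expect_equal(d, 0.25)
  expect_error(robust_roi_comparison(a[0, ], b), "non-empty")
})
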