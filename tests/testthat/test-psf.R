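test_that("Gaussian FWHM fitting recovers sigma on exact profiles", {
  x <- seq(-3, 3, by = 0.25)
  fit <- fit_gaussian_fwhm(x, 5 + 10 * exp(-x^2 / 2))
  expect_true(fit$converged)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)), tolerance = 1e-6)
  expect_equal(fit$fwhm, fit$sigma * 2 * sqrt(2 * log(2)))  # exact identity
  # sigma chosen so the FWHM is the 0.68 um lateral resolution
  fit2 <- fit_gaussian_fwhm(x, 2 + exp(-x^2 / (2 * 0.2887^2)))
  expect_equal(fit2$fwhm, 0.68, tolerance = 5e-3)
  expect_equal(tidy(fit)$estimate[3], fit$fwhm)
})

test_that("flat or degenerate profiles yield explicit fit failures", {
  x <- seq(-2, 2, length.out = 11)
  flat <- fit_gaussian_fwhm(x, rep(3, 11))
  expect_false(flat$converged)
  expect_true(is.na(flat$fwhm))
  expect_error(fit_gaussian_fwhm(1:3, 1:3), "5 samples")
})

test_that("FWHM estimate is unbiased to < 0.5% on noiseless sampled Gaussians", {
  for (sig in c(0.3, 1, 2.5)) {
    x <- seq(-3 * sig, 3 * sig, length.out = 15)
    fit <- fit_gaussian_fwhm(x, 1 + 4 * exp(-x^2 / (2 * sig^2)))
    expect_lt(abs(fit$fwhm / (2 * sqrt(2 * log(2)) * sig) - 1), 0.005)
  }
})

test_that("3-D bead fitting recovers lateral and axial FWHM within 2%", {
  up <- 0.1; zs <- 0.5
  sx <- 0.68 / (2 * sqrt(2 * log(2)))   # 0.2887 um
  sz <- 8.49 / (2 * sqrt(2 * log(2)))   # 3.605 um
  xs <- (seq_len(64) - 0.5) * up
  zq <- (seq_len(49) - 0.5) * zs
  cx <- xs[32]; cz <- zq[25]
  gx <- exp(-(xs - cx)^2 / (2 * sx^2))
  stack <- array(0, c(49, 64, 64))
  for (z in 1:49) {
    stack[z, , ] <- 50 + 200 * exp(-(zq[z] - cz)^2 / (2 * sz^2)) * (gx %o% gx)
  }
  st <- movie_stack(stack, fps = 1, um_per_px = up)
  fit <- bead_fwhm_3d(st, c(32, 32), z_step_um = zs)
  expect_equal(fit$lateral$fwhm, 0.68, tolerance = 0.02)
  expect_equal(fit$axial$fwhm, 8.49, tolerance = 0.02)

  # isotropic bead: lateral equals axial FWHM (z sampled like x)
  iso <- array(0, c(64, 64, 64))
  g1 <- exp(-(xs - cx)^2 / (2 * 0.5^2))
  for (z in 1:64) iso[z, , ] <- 10 + 100 * g1[z] * (g1 %o% g1)
  fit_iso <- bead_fwhm_3d(movie_stack(iso, 1, up), c(32, 32), z_step_um = up)
  expect_equal(fit_iso$lateral$fwhm, fit_iso$axial$fwhm, tolerance = 1e-3)

  # refractive-index scaling stretches the axial estimate by the same factor
  fit_sc <- bead_fwhm_3d(st, c(32, 32), z_step_um = zs, axial_scale = 1.33)
  expect_equal(fit_sc$axial$fwhm, 1.33 * fit$axial$fwhm, tolerance = 1e-6)

  # bead at the stack edge is rejected
  edge <- array(0, c(9, 64, 64))
  for (z in 1:9) edge[z, , ] <- (z == 9) * (g1 %o% g1)
  expect_error(bead_fwhm_3d(movie_stack(edge, 1, up), c(32, 32), z_step_um = up),
               "edge")
})

test_that("signal-to-background ratio matches hand computation and is scale-free", {
  img <- matrix(5, 41, 41)
  img[21, 21] <- 50
  r <- signal_to_background(img, c(21, 21), um_per_px = 1)
  expect_equal(r, 10)
  expect_equal(signal_to_background(matrix(7, 41, 41), c(21, 21), um_per_px = 1), 1)
  # invariant under positive rescaling
  expect_equal(signal_to_background(3.7 * img, c(21, 21), um_per_px = 1), r)
  expect_error(signal_to_background(img, c(2, 2), um_per_px = 1), "square")
})

test_that("depth profile comparison uses the exact rank-sum distribution", {
  tbl <- tibble::tibble(
    depth_um = rep(c(5, 210), each = 10),
    mode = rep(rep(c("confocal", "widefield"), each = 5), 2),
    sbr = c(rep(4, 10),                 # identical at 5 um
            10:14, 1:5)                 # fully separated at 210 um
  )
  prof <- sbr_depth_profile(tbl)
  expect_equal(nrow(prof), 2)
  # identical samples: no evidence of difference
  expect_equal(prof$p[prof$depth_um == 5], 1)
  # fully separated n = 5 vs 5: the extreme rank assignment, p = 2/choose(10,5)
  expect_equal(prof$W[prof$depth_um == 210], 25)
  expect_equal(prof$p[prof$depth_um == 210], 2 / choose(10, 5))
  expect_error(sbr_depth_profile(tbl[tbl$mode == "confocal", ]), "two modes")
})

test_that("confocal beats widefield signal-to-background deep in a phantom", {
  beads <- data.frame(x_um = c(50.5, 20.5, 80.5), y_um = c(50.5, 80.5, 20.5),
                      z_um = c(210, 40, 120))
  args <- list(bead_positions_um = beads, depths_um = c(5, 210),
               field_um = c(101, 101), um_per_px = 1,
               attenuation_length_um = 300)
  conf <- do.call(generate_bead_phantom, c(args, mode = "confocal"))
  wf <- do.call(generate_bead_phantom, c(args, mode = "widefield"))
  sb_c <- signal_to_background(conf$data[2, , ], c(51, 51), um_per_px = 1)
  sb_w <- signal_to_background(wf$data[2, , ], c(51, 51), um_per_px = 1)
  expect_gte(sb_c, sb_w)
})
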