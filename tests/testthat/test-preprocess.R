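make_raw <- function(px, nch = dim(px)[3]) {
  spectral_cube(px, channels = default_channel_table()[seq_len(nch), ])
}

test_that("CDF 9/7 transform reconstructs perfectly at any size", {
  set.seed(2)
  for (dims in list(c(16, 16), c(30, 41), c(9, 13))) {
    img <- matrix(rnorm(prod(dims)), dims[1])
    w <- afmicell:::cdf97_fwd2d(img, 2L)
    expect_lt(max(abs(afmicell:::cdf97_inv2d(w) - img)), 1e-12)
  }
})

test_that("reference smoothing is gentle on smooth spectra, denoises, and is near-idempotent", {
  x <- 3 + 0.5 * seq_len(47) / 47 - 0.3 * (seq_len(47) / 47)^2  # quadratic
  expect_equal(smooth_reference(rep(2, 47)), rep(2, 47), tolerance = 1e-10)
  set.seed(4)
  noisy <- x + rnorm(47, 0, 0.2)
  sm <- smooth_reference(noisy)
  expect_lt(sqrt(mean((sm - x)^2)), sqrt(mean((noisy - x)^2)))
  twice <- smooth_reference(sm)
  expect_lt(sqrt(mean((twice - sm)^2)) / sqrt(mean(sm^2)), 0.01)
  expect_warning(out <- smooth_reference(1:5), "too short")
  expect_identical(out, 1:5)
})

test_that("cosmic-ray removal replaces exactly the injected spike on a constant cube", {
  px <- array(5, c(12, 12, 3))
  px[6, 7, 2] <- 500
  cube <- remove_cosmic_rays(make_raw(px))
  expect_equal(cube$n_spikes, 1L)
  expect_equal(cube$pixels[6, 7, 2], 5)
  expect_equal(cube$pixels, array(5, c(12, 12, 3)))

  clean <- remove_cosmic_rays(make_raw(array(5, c(12, 12, 3))))
  expect_equal(clean$n_spikes, 0L)
})

test_that("pipeline order is enforced through the stage/step tags", {
  px <- array(1, c(8, 8, 2))
  cube <- make_raw(px)
  mask <- mask_image(matrix(0L, 8, 8))
  expect_error(denoise_lowrank(cube), "requires 'cosmic'")
  cube <- remove_cosmic_rays(cube)
  expect_error(remove_cosmic_rays(cube), "already")
  expect_error(subtract_background(cube, mask), "requires 'denoise'")
})

test_that("low-rank denoising is exact on low-rank scenes and reduces noise", {
  set.seed(6)
  # spatially smooth rank-3 scene: abundance maps are separable bumps
  bump <- function(cx, cy) as.vector(outer(exp(-(1:20 - cx)^2 / 30),
                                           exp(-(1:20 - cy)^2 / 30)))
  A <- cbind(bump(6, 7), bump(14, 12), bump(10, 16)) + 0.1
  E <- matrix(runif(3 * 10) + 0.2, 3, 10)        # endmembers
  truth <- array(A %*% E, c(20, 20, 10))
  cfg3 <- preprocess_config(denoise_rank = 3L, denoise_wavelet_levels = 0L)
  cube <- make_raw(truth)
  cube$steps <- "cosmic"
  out <- denoise_lowrank(cube, cfg3)
  expect_lt(sqrt(mean((out$pixels - truth)^2)) / sqrt(mean(truth^2)), 1e-6)

  noisy <- truth + array(rnorm(length(truth), 0, 0.05 * mean(truth)),
                         dim(truth))
  noisy[noisy < 0] <- 0
  cube2 <- make_raw(noisy); cube2$steps <- "cosmic"
  den <- denoise_lowrank(cube2, preprocess_config(denoise_rank = 3L))
  expect_lt(sqrt(mean((den$pixels - truth)^2)),
            sqrt(mean((noisy - truth)^2)))

  # identity configuration
  cube3 <- make_raw(noisy); cube3$steps <- "cosmic"
  idn <- denoise_lowrank(cube3, preprocess_config(
    denoise_rank = 10L, denoise_wavelet_levels = 0L))
  expect_equal(idn$pixels, noisy, tolerance = 1e-12)
  expect_error(denoise_lowrank(cube3, preprocess_config(denoise_rank = 11L)),
               "exceeds")
})

test_that("background subtraction removes a uniform offset exactly", {
  set.seed(7)
  px <- array(0, c(10, 10, 3))
  offs <- c(2, 5, 1)
  for (k in 1:3) px[, , k] <- offs[k]
  px[4:6, 4:6, ] <- px[4:6, 4:6, ] + 10      # a "cell"
  mask <- matrix(0L, 10, 10); mask[4:6, 4:6] <- 1L
  cube <- make_raw(px); cube$steps <- c("cosmic", "denoise")
  out <- subtract_background(cube, mask_image(mask))
  expect_equal(out$background_levels, offs)
  expect_true(all(out$pixels[, , 1][mask == 0] == 0))
  expect_equal(out$pixels[5, 5, 2], 10)

  zero <- make_raw(array(0, c(4, 4, 1)) + 3)
  zero$pixels[, , 1] <- c(rep(0, 12), rep(3, 4))
  zero$steps <- c("cosmic", "denoise")
  m0 <- matrix(0L, 4, 4); m0[, 4] <- 1L
  out0 <- subtract_background(zero, mask_image(m0))
  expect_equal(out0$background_levels, 0)

  full <- mask_image(matrix(1L, 10, 10))
  cube2 <- make_raw(px); cube2$steps <- c("cosmic", "denoise")
  expect_error(subtract_background(cube2, full), "background")
})

test_that("flat-field correction is a no-op for uniform illumination and degree 0", {
  px <- array(3, c(12, 12, 2))
  mask <- matrix(0L, 12, 12); mask[5:7, 5:7] <- 1L
  cube <- make_raw(px); cube$steps <- c("cosmic", "denoise")
  cube <- subtract_background(cube, mask_image(mask))
  before <- cube$pixels
  out <- flatten_field(cube, mask_image(mask))
  expect_equal(out$pixels, before, tolerance = 1e-8)

  cube0 <- make_raw(px); cube0$steps <- c("cosmic", "denoise")
  cube0 <- subtract_background(cube0, mask_image(mask))
  out0 <- flatten_field(cube0, mask_image(mask),
                        preprocess_config(flatfield_poly_degree = 0L))
  expect_equal(out0$pixels, before, tolerance = 1e-8)
})

test_that("flat-field correction recovers a multiplicative ramp", {
  n <- 40
  ramp <- outer(seq(0.8, 1.2, length.out = n), rep(1, n))
  ramp <- ramp / mean(ramp)
  bg <- 0.5
  cell_val <- 10
  mask <- matrix(0L, n, n); mask[18:22, 18:22] <- 1L
  sig <- matrix(0, n, n); sig[mask == 1L] <- cell_val
  px <- array((sig + bg) * ramp, c(n, n, 1))
  cube <- make_raw(px); cube$steps <- c("cosmic", "denoise")
  cube <- subtract_background(cube, mask_image(mask))
  out <- flatten_field(cube, mask_image(mask))
  vals <- out$pixels[, , 1][mask == 1L]
  expect_lt(stats::sd(vals) / mean(vals), 0.01)   # CoV under 1%
})

test_that("calibration applies reference-derived gains and validates inputs", {
  px <- array(2, c(6, 6, 3))
  cube <- make_raw(px)
  cube$steps <- c("cosmic", "denoise", "background", "flatten")
  ident <- reference_spectra(rep(0, 3), c(1, 2, 3), c(1, 2, 3))
  out <- calibrate(cube, ident)
  expect_equal(out$gains, rep(1, 3))
  expect_equal(out$pixels, px)
  expect_identical(out$stage, "calibrated")

  # calibrating the calibration-fluid cube reproduces the reference
  meas <- c(2, 4, 1.5); ref <- c(3, 1, 2); water <- c(0.2, 0.4, 0.1)
  fluid <- array(0, c(4, 4, 3))
  for (k in 1:3) fluid[, , k] <- meas[k] - water[k]
  cf <- make_raw(fluid)
  cf$steps <- c("cosmic", "denoise", "background", "flatten")
  got <- calibrate(cf, reference_spectra(water, meas, ref))
  for (k in 1:3) expect_equal(got$pixels[, , k], matrix(ref[k], 4, 4),
                              tolerance = 1e-6)

  bad <- reference_spectra(c(2, 0, 0), c(1, 2, 3), c(1, 1, 1))
  cube2 <- make_raw(px)
  cube2$steps <- c("cosmic", "denoise", "background", "flatten")
  expect_error(calibrate(cube2, bad), "channel\\(s\\) 0")
})

test_that("every stage preserves shape, channel order and non-negativity", {
  f <- render_test_field(seed = 13L, noise_on = TRUE)
  refs <- simulate_references(f$scenario)
  cube <- f$rf$cube
  d0 <- dim(cube$pixels)
  for (step in c("cosmic", "denoise", "background", "flatten", "calibrate")) {
    cube <- switch(step,
      cosmic = remove_cosmic_rays(cube),
      denoise = denoise_lowrank(cube),
      background = subtract_background(cube, f$rf$mask),
      flatten = flatten_field(cube, f$rf$mask),
      calibrate = calibrate(cube, refs$refs))
    expect_identical(dim(cube$pixels), d0)
    expect_true(all(is.finite(cube$pixels)))
    expect_gte(min(cube$pixels), 0)
  }
  expect_identical(cube$stage, "calibrated")
})

test_that("known per-channel gain distortions are inverted by calibration", {
  f <- render_test_field(seed = 17L, noise_on = FALSE)
  refs <- simulate_references(f$scenario)
  cal <- preprocess_cube(f$rf$cube, f$rf$mask, refs$refs)
  # applied gain x true response should be 1 in every channel
  expect_lt(sqrt(mean((cal$gains * f$scenario$instrument_response - 1)^2)),
            0.02)
})
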