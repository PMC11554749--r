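test_that("simulation is bit-reproducible under its seed", {
  a <- suppressWarnings(simulate_cells(afmi_scenario(cells_per_class = 10L,
                                                     seed = 5L)))
  b <- suppressWarnings(simulate_cells(afmi_scenario(cells_per_class = 10L,
                                                     seed = 5L)))
  expect_identical(a$features, b$features)
  expect_identical(a$cells, b$cells)
  c_ <- suppressWarnings(simulate_cells(afmi_scenario(cells_per_class = 10L,
                                                      seed = 6L)))
  expect_false(identical(a$features, c_$features))
})

test_that("passage logs increase to arrest, then stall, and differ between lines", {
  log_df <- simulate_passage_log(afmi_scenario(seed = 8L))
  for (ln in unique(log_df$line_id)) {
    cum <- log_df$cumulative_doublings[log_df$line_id == ln]
    inc <- diff(cum)
    expect_true(all(inc[-length(inc)] > 0))
    expect_equal(inc[length(inc)], 0)            # confirmed arrest
    expect_gte(max(cum), 20); expect_lte(max(cum), 30)
  }
  arrests <- tapply(log_df$cumulative_doublings, log_df$line_id, max)
  expect_gt(length(unique(round(arrests, 6))), 1L)
})

test_that("emitted doubling labels are consistent with the passage log", {
  sim <- suppressWarnings(simulate_cells(afmi_scenario(cells_per_class = 8L,
                                                       seed = 9L)))
  rederived <- make_doubling_labels(sim$cells, sim$passage_log)
  expect_identical(rederived, sim$cells$doublings_remaining)
  expect_true(all(sim$cells$doublings_remaining >= 0))
  expect_lte(length(sim$classes), 29L)
})

test_that("zero heterogeneity and noise make same-condition cells identical", {
  drift <- c(nadh = -0.35, fad = 0.25, lipofuscin = 0.45, collagen = 0)
  sc <- afmi_scenario(cells_per_class = 12L,
                      aging = list(drift = drift, amplitude = 1,
                                   heterogeneity_sd = 0),
                      line_effects_sd = 0, measurement_noise_sd = 0,
                      senescent_prob = function(dr) rep(0, length(dr)),
                      stro1_prob = function(dr) rep(0, length(dr)),
                      seed = 10L)
  sim <- suppressWarnings(simulate_cells(sc))
  sub <- sim$cells$cycle_phase == "G1" & sim$cells$alp == "neg"
  one_class <- sim$cells$doublings_remaining ==
    sim$cells$doublings_remaining[which(sub)[1]]
  rows <- which(sub & one_class)
  if (length(rows) > 1) {
    sp <- sim$spectra[rows, , drop = FALSE]
    expect_lt(max(apply(sp, 2, function(v) diff(range(v)))), 1e-12)
  }
})

test_that("rendered fields keep geometry and bookkeeping honest", {
  f <- render_test_field(seed = 51L, noise_on = TRUE)
  expect_identical(sort(mask_cell_ids(f$rf$mask)),
                   sort(f$sim$cells$cell_id[1:4]))
  expect_identical(dim(f$rf$cube$pixels)[1:2], dim(f$rf$mask$labels))
  expect_identical(f$rf$cube$stage, "raw")
  # spike bookkeeping: recorded indices are genuinely spiked
  spk <- f$rf$truth$spike_index
  if (length(spk)) {
    clean <- render_field(f$sim$cells[1:4, ], f$sim$spectra[1:4, ],
                          f$scenario, noise_on = FALSE,
                          seed = 52L)
    expect_true(all(f$rf$cube$pixels[spk] >
                      0.5 * f$scenario$noise$cosmic_amplitude))
  }
})

test_that("hypertrophic senescent cells are rendered about (factor)^2 larger", {
  sc <- afmi_scenario(seed = 53L)
  cells <- data.frame(cell_id = 1:2, radius_px = c(8, 8 * 1.8),
                      axis_ratio = c(0.8, 0.8), angle = c(0.4, 1.1))
  sp <- matrix(1, 2, 47)
  rf <- render_field(cells, sp, sc, noise_on = FALSE, seed = 3L)
  a1 <- sum(rf$mask$labels == 1L); a2 <- sum(rf$mask$labels == 2L)
  expect_gt(a2 / a1, 1.8^2 * 0.85)
  expect_lt(a2 / a1, 1.8^2 * 1.15)
})

test_that("overcrowded fields are rejected with advice", {
  sc <- afmi_scenario(seed = 54L)
  cells <- data.frame(cell_id = 1:5, radius_px = rep(30, 5),
                      axis_ratio = 1, angle = 0)
  expect_error(render_field(cells, matrix(1, 5, 47), sc, seed = 1L),
               "cells_per_field|at most")
})

test_that("reference simulation inverts through calibrate to the stored gains", {
  sc <- afmi_scenario(seed = 55L)
  r0 <- simulate_references(sc)
  gains <- r0$refs$calib_reference / (r0$refs$calib_measured -
                                        r0$refs$water_mean)
  expect_equal(gains, r0$gains_truth, tolerance = 1e-9)

  rn <- simulate_references(sc, noise_sd = 0.01, seed = 7L)
  sm <- reference_spectra(smooth_reference(rn$refs$water_mean),
                          smooth_reference(rn$refs$calib_measured),
                          smooth_reference(rn$refs$calib_reference))
  g <- sm$calib_reference / (sm$calib_measured - sm$water_mean)
  expect_lt(sqrt(mean((g / rn$gains_truth - 1)^2)), 0.03)
})

test_that("the senescence effect dial moves the cross-validated AUC monotonically", {
  aucs <- vapply(c(0.3, 0.6, 1.2), function(shift) {
    b <- simulate_channel_shift(n = 160, shift_sd = shift, seed = 19L)
    crossvalidate(b$features, b$labels, classifier_spec("linear_svm"),
                  n_folds = 4L, seed = 3L)$auc_mean
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("a null spectral scenario drives classification to chance", {
  b <- simulate_channel_shift(n = 200, shift_sd = 0, seed = 20L)
  rep0 <- crossvalidate(b$features, b$labels, classifier_spec("linear_svm"),
                        seed = 3L)
  expect_gt(rep0$auc_mean, 0.35)
  expect_lt(rep0$auc_mean, 0.65)
})

test_that("scenario validation rejects negative dispersion", {
  expect_error(afmi_scenario(line_effects_sd = -1), "non-negative")
  drift <- c(nadh = 0, fad = 0, lipofuscin = 0, collagen = 0)
  expect_error(afmi_scenario(aging = list(drift = drift, amplitude = 1,
                                          heterogeneity_sd = -0.1)),
               "non-negative")
})
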