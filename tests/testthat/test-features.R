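calibrated_cube <- function(px, nch = dim(px)[3]) {
  spectral_cube(px, channels = default_channel_table()[seq_len(nch), ],
                stage = "calibrated")
}

test_that("intensity features follow their closed forms and conventions", {
  px <- array(0, c(6, 6, 2))
  px[2:4, 2:4, 1] <- 3          # constant cell, channel 1
  px[2:4, 2:4, 2] <- 1.5
  mask <- matrix(0L, 6, 6); mask[2:4, 2:4] <- 1L
  v <- extract_intensity_features(calibrated_cube(px), mask_image(mask), 1L,
                                  feature_config(ratio_channels = c(0L, 1L)))
  expect_equal(v[["ch00_mean"]], 3)
  expect_equal(v[["ch00_median"]], 3)
  expect_equal(v[["ch00_sd"]], 0)
  expect_equal(v[["ch00_skew"]], 0)   # zero-SD convention
  expect_equal(v[["ch00_kurt"]], 0)
  expect_equal(v[["ratio_ch00_ch01"]], 2, tolerance = 1e-6)

  # two-pixel cell {1, 3}: mean 2, n-1 SD = sqrt(2)
  px2 <- array(0, c(4, 4, 1))
  px2[1, 1, 1] <- 1; px2[1, 2, 1] <- 3
  m2 <- matrix(0L, 4, 4); m2[1, 1:2] <- 5L
  v2 <- extract_intensity_features(calibrated_cube(px2), mask_image(m2), 5L,
                                   feature_config(ratio_channels = integer()))
  expect_equal(v2[["ch00_mean"]], 2)
  expect_equal(v2[["ch00_sd"]], sqrt(2))

  expect_error(extract_intensity_features(calibrated_cube(px2),
                                          mask_image(m2), 9L), "empty")
  raw <- spectral_cube(px2, channels = default_channel_table()[1, ])
  expect_error(extract_intensity_features(raw, mask_image(m2), 5L),
               "calibrated")
})

test_that("noise-free generator cells have channel means equal to their mixture spectra", {
  f <- render_test_field(seed = 23L, noise_on = FALSE, n_cells = 3L)
  sig <- f$rf$truth$signal
  cube <- spectral_cube(sig, channels = f$scenario$channels,
                        field_id = "t", stage = "calibrated")
  for (i in 1:3) {
    id <- f$sim$cells$cell_id[i]
    v <- extract_intensity_features(cube, f$rf$mask, id,
                                    feature_config(ratio_channels = integer()))
    means <- v[sprintf("ch%02d_mean", 0:46)]
    expect_equal(unname(means), unname(f$sim$spectra[i, ]),
                 tolerance = 1e-6)
  }
})

test_that("GLCM texture matches the hand-computed checkerboard and conventions", {
  board <- array(0, c(4, 4, 1))
  board[, , 1] <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  mask <- matrix(1L, 4, 4)
  cfg <- feature_config(glcm_offsets = list(c(0L, 1L)),
                        ratio_channels = integer())
  v <- extract_texture_features(calibrated_cube(board), mask_image(mask),
                                1L, cfg)
  expect_equal(v[["ch00_glcm_contrast"]], 15^2)   # levels 1 and 16
  expect_equal(v[["ch00_glcm_energy"]], 0.5)

  flat <- calibrated_cube(array(2, c(4, 4, 1)))
  vf <- extract_texture_features(flat, mask_image(mask), 1L, cfg)
  expect_equal(unname(vf), c(0, 0, 1, 1, 0))

  # the GLCM itself is a probability distribution
  set.seed(3)
  img <- array(runif(25), c(5, 5, 1))
  q <- matrix(1L + pmin(15, floor((img[, , 1] - min(img)) /
                                   diff(range(img)) * 16)), 5)
  P <- afmicell:::glcm_matrix(q, matrix(TRUE, 5, 5), 16L,
                              list(c(0L, 1L), c(1L, 0L)))
  expect_equal(sum(P), 1, tolerance = 1e-12)
  expect_true(isSymmetric(P))

  tiny <- matrix(0L, 4, 4); tiny[1, 1:2] <- 1L
  expect_error(extract_texture_features(calibrated_cube(board),
                                        mask_image(tiny), 1L, cfg),
               "3x3")
})

test_that("morphology features match geometry on squares, disks and ellipses", {
  sq <- matrix(0L, 14, 14); sq[3:12, 3:12] <- 1L
  v <- extract_morphology_features(mask_image(sq), 1L, pixel_size_um = 1)
  expect_equal(v[["morph_area_um2"]], 100)
  expect_equal(v[["morph_extent"]], 1.0)
  expect_equal(v[["morph_solidity"]], 1.0, tolerance = 1e-9)

  n <- 51; r <- 20
  disk <- matrix(0L, n, n)
  disk[outer(1:n, 1:n, function(i, j) (i - 26)^2 + (j - 26)^2 <= r^2)] <- 2L
  vd <- extract_morphology_features(mask_image(disk), 2L)
  expect_gt(vd[["morph_circularity"]], 0.85)
  expect_lt(vd[["morph_circularity"]], 1.05)
  expect_lt(vd[["morph_eccentricity"]], 0.1)
  expect_equal(vd[["morph_equiv_diameter_um"]], 2 * sqrt(sum(disk > 0) / pi))

  ell <- matrix(0L, 61, 61)
  ell[outer(1:61, 1:61, function(i, j)
    ((i - 31) / 28)^2 + ((j - 31) / 9)^2 <= 1)] <- 3L
  ve <- extract_morphology_features(mask_image(ell), 3L)
  expect_gt(ve[["morph_eccentricity"]], vd[["morph_eccentricity"]])
  expect_gt(ve[["morph_major_axis_um"]], ve[["morph_minor_axis_um"]])
})

test_that("DNA-content gating splits a bimodal population at the configured thresholds", {
  set.seed(9)
  m <- 1000
  g1 <- rnorm(140, m, 0.05 * m)
  g2 <- rnorm(60, 2 * m, 0.05 * m)
  ph <- gate_dna_content(c(g1, g2))
  expect_true(all(ph[141:200] == "G2"))
  expect_true(mean(ph[1:140] == "G1") > 0.95)

  allg1 <- gate_dna_content(rnorm(100, m, 0.02 * m))
  expect_true(all(allg1 == "G1"))

  # generator mixture: 70/15/15 recovered with >= 90% accuracy
  sim <- suppressWarnings(simulate_cells(
    afmi_scenario(cells_per_class = 20L, seed = 31L)))
  ph2 <- gate_dna_content(sim$cells$dapi_total)
  expect_gt(mean(as.character(ph2) == sim$cells$cycle_phase), 0.9)
})

test_that("stain positivity gating uses background/area normalisation and Otsu", {
  set.seed(10)
  areas <- runif(60, 80, 120)
  bg <- 2
  score_true <- c(rnorm(30, 1), rnorm(30, 8))
  totals <- (score_true + bg) * areas
  call <- gate_stain_positivity(totals, bg, areas)
  expect_identical(as.character(call), rep(c("neg", "pos"), each = 30))

  expect_warning(flat <- gate_stain_positivity(rep(100, 5), 0, rep(10, 5)),
                 "degenerate")
  expect_true(all(flat == "neg"))

  abs_call <- gate_stain_positivity(c(50, 150), 0, c(10, 10),
                                    list(method = "absolute", value = 10))
  expect_identical(as.character(abs_call), c("neg", "pos"))
  expect_error(gate_stain_positivity(1, 0, 0), "positive")
})

test_that("clean_and_assemble joins, drops bad rows and filters correlated features", {
  set.seed(11)
  n <- 500
  f <- data.frame(field_id = "F1", cell_id = seq_len(n),
                  a = rnorm(n), b = rnorm(n), c = rnorm(n))
  f$a_copy <- f$a                              # r = 1 duplicate
  out <- suppressMessages(clean_and_assemble(f))
  expect_true(xor("a" %in% names(out), "a_copy" %in% names(out)))
  # independent noise columns are never removed at this n
  expect_true(all(c("b", "c") %in% names(out)))

  f2 <- f[1:10, ]; f2$b[3] <- NaN
  out2 <- suppressMessages(clean_and_assemble(f2))
  expect_equal(nrow(out2), 9L)
  expect_equal(attr(out2, "dropped_cells"), 1L)

  lab <- data.frame(field_id = "F1", cell_id = 1:10,
                    senescent = rep(c("pos", "neg"), 5))
  out3 <- suppressMessages(clean_and_assemble(f[1:10, ], lab))
  expect_true("senescent" %in% names(out3))

  dup <- rbind(f[1:3, ], f[1, ])
  expect_error(suppressMessages(clean_and_assemble(dup)), "collision")
})

test_that("feature catalog determines the extracted column set", {
  cfg <- feature_config()
  cat_ <- feature_catalog(cfg, 47L)
  expect_equal(sum(cat_$family == "intensity"), 7 * 47)
  expect_equal(sum(cat_$family == "texture"), 5 * 47)
  expect_equal(sum(cat_$family == "morphology"), 9)
  expect_false(anyDuplicated(cat_$name) > 0)

  f <- render_test_field(seed = 37L, noise_on = FALSE, n_cells = 2L)
  cube <- spectral_cube(f$rf$truth$signal, channels = f$scenario$channels,
                        stage = "calibrated", field_id = "t")
  tab <- extract_cell_features(cube, f$rf$mask, cfg)
  expect_identical(setdiff(names(tab), c("field_id", "cell_id")), cat_$name)
  expect_equal(nrow(tab), 2L)
})
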