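# Raw cube -> calibrated cube. Enforced order:
# cosmic rays -> denoise -> background -> flat-field -> calibration.

#' Preprocessing configuration
#'
#' @param cosmic_ray_zscore robust z threshold for spike detection.
#' @param denoise_rank singular components retained in the spectral
#'   low-rank step; must not exceed the channel count.
#' @param denoise_wavelet_levels 2-D wavelet shrinkage depth per channel
#'   (0 disables the wavelet step).
#' @param flatfield_poly_degree degree of the 2-D illumination polynomial.
#' @param wavelet_name wavelet family label (informational; the CDF 9/7
#'   biorthogonal pair is the implemented transform).
#' @param epsilon guard for divisions.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(cosmic_ray_zscore = 8, denoise_rank = 8L,
                              denoise_wavelet_levels = 2L,
                              flatfield_poly_degree = 2L,
                              wavelet_name = "cdf97", epsilon = 1e-9) {
  if (cosmic_ray_zscore <= 0) stopf("cosmic_ray_zscore must be positive")
  structure(list(cosmic_ray_zscore = cosmic_ray_zscore,
                 denoise_rank = as.integer(denoise_rank),
                 denoise_wavelet_levels = as.integer(denoise_wavelet_levels),
                 flatfield_poly_degree = as.integer(flatfield_poly_degree),
                 wavelet_name = wavelet_name, epsilon = epsilon),
            class = "preprocess_config")
}

# reflect-101 index vector: out-of-range neighbours mirror without
# repeating the edge pixel (so a pixel is never its own neighbour).
reflect_idx <- function(i, n) {
  i[i < 1L] <- 2L - i[i < 1L]
  i[i > n] <- 2L * n - i[i > n]
  i
}

# Row-wise sort of a small-column matrix by vectorised compare-exchange
# (bubble network); fast enough for the 8/9-column neighbour stacks.
row_sort <- function(N) {
  k <- ncol(N)
  for (a in seq_len(k - 1L)) for (b in seq_len(k - a)) {
    lo <- pmin(N[, b], N[, b + 1L]); hi <- pmax(N[, b], N[, b + 1L])
    N[, b] <- lo; N[, b + 1L] <- hi
  }
  N
}

neighbour_stack <- function(img, include_center = FALSE) {
  r <- nrow(img); cc <- ncol(img)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  if (include_center) shifts <- c(shifts, list(c(0, 0)))
  N <- matrix(0, r * cc, length(shifts))
  for (s in seq_along(shifts)) {
    ri <- reflect_idx(seq_len(r) + shifts[[s]][1], r)
    cj <- reflect_idx(seq_len(cc) + shifts[[s]][2], cc)
    N[, s] <- as.vector(img[ri, cj])
  }
  N
}

row_median <- function(N) {
  S <- row_sort(N)
  k <- ncol(S)
  if (k %% 2L) S[, (k + 1L) %/% 2L]
  else (S[, k %/% 2L] + S[, k %/% 2L + 1L]) / 2
}

# Median and robust SD (1.4826 x MAD) of the full 3x3 neighbourhood of
# every pixel in a plane (centre included; reflect-101 edges). Including
# the centre keeps the 9-sample MAD from collapsing when the centre is a
# moderate fluctuation, which holds the false-spike rate down.
neighbour_stats <- function(img) {
  r <- nrow(img); cc <- ncol(img)
  N <- neighbour_stack(img, include_center = TRUE)
  med <- row_median(N)
  mad <- row_median(abs(N - med)) * 1.4826
  list(median = matrix(med, r, cc), rsd = matrix(mad, r, cc))
}

#' Remove cosmic-ray spikes
#'
#' A pixel is a spike when it exceeds the median of its 3x3 spatial
#' neighbourhood (same channel, centre included) by more than
#' `cosmic_ray_zscore` robust standard deviations (1.4826 x MAD) of that
#' neighbourhood. Spikes are replaced by the neighbourhood median.
#'
#' @param cube raw [spectral_cube()].
#' @param config a [preprocess_config()].
#' @return the cube with spikes replaced; the spike count is stored in
#'   `cube$n_spikes` and per-spike indices in `cube$spike_index`.
#' @export
remove_cosmic_rays <- function(cube, config = preprocess_config()) {
  check_step_order(cube, "cosmic")
  d <- dim(cube$pixels)
  n_spikes <- 0L
  idx_all <- integer()
  for (k in seq_len(d[3])) {
    img <- cube$pixels[, , k]
    ns <- neighbour_stats(img)
    spike <- img - ns$median > config$cosmic_ray_zscore * ns$rsd
    if (any(spike)) {
      img[spike] <- ns$median[spike]
      cube$pixels[, , k] <- img
      n_spikes <- n_spikes + sum(spike)
      idx_all <- c(idx_all, which(spike) + (k - 1L) * d[1] * d[2])
    }
  }
  cube$n_spikes <- n_spikes
  cube$spike_index <- idx_all
  cube$steps <- c(cube$steps, "cosmic")
  advance_stage(cube, "preprocessed")
}

#' Low-rank plus wavelet denoising
#'
#' Reshapes the cube to a (pixels x channels) matrix, retains the top
#' `denoise_rank` singular components (cell autofluorescence spectra live
#' in a low-dimensional endmember subspace), then applies per-channel 2-D
#' CDF 9/7 wavelet shrinkage and clips at zero.
#'
#' @param cube cube after [remove_cosmic_rays()].
#' @param config a [preprocess_config()].
#' @return denoised cube.
#' @export
denoise_lowrank <- function(cube, config = preprocess_config()) {
  check_step_order(cube, "denoise", "cosmic")
  d <- dim(cube$pixels)
  if (config$denoise_rank > d[3])
    stopf("denoise_rank (%d) exceeds the channel count (%d)",
          config$denoise_rank, d[3])
  X <- matrix(cube$pixels, d[1] * d[2], d[3])
  if (config$denoise_rank < d[3]) {
    sv <- svd(X, nu = config$denoise_rank, nv = config$denoise_rank)
    r <- config$denoise_rank
    X <- sv$u %*% (sv$d[seq_len(r)] * t(sv$v))
  }
  out <- array(X, d)
  if (config$denoise_wavelet_levels > 0L) {
    for (k in seq_len(d[3]))
      out[, , k] <- wavelet_denoise2d(out[, , k], config$denoise_wavelet_levels)
  }
  clipped <- sum(out < 0)
  if (clipped > 0) out[out < 0] <- 0
  cube$pixels <- out
  cube$n_clipped_denoise <- clipped
  cube$steps <- c(cube$steps, "denoise")
  cube
}

#' Subtract the per-channel background level
#'
#' The background is the median intensity over mask == 0 pixels, per
#' channel; negatives after subtraction are clipped at zero (count logged
#' on the cube). The pre-subtraction pixel data are retained on the cube
#' for the flat-field stage, which estimates illumination from them.
#'
#' @param cube cube after [denoise_lowrank()].
#' @param mask the field's [mask_image()].
#' @param config a [preprocess_config()].
#' @return background-subtracted cube with `cube$background_levels` set.
#' @export
subtract_background <- function(cube, mask, config = preprocess_config()) {
  check_step_order(cube, "background", "denoise")
  bg <- mask$labels == 0L
  if (!any(bg)) stopf("mask has no background pixels; cannot estimate background")
  d <- dim(cube$pixels)
  cube$presub <- cube$pixels
  levels <- numeric(d[3])
  clipped <- 0L
  for (k in seq_len(d[3])) {
    img <- cube$pixels[, , k]
    levels[k] <- stats::median(img[bg])
    img <- img - levels[k]
    clipped <- clipped + sum(img < 0)
    img[img < 0] <- 0
    cube$pixels[, , k] <- img
  }
  cube$background_levels <- levels
  cube$n_clipped_background <- clipped
  cube$steps <- c(cube$steps, "background")
  cube
}

# Design matrix of 2-D polynomial terms x^i y^j, i + j <= degree,
# on normalised coordinates.
poly2d_terms <- function(xi, yj, degree) {
  cols <- list()
  for (i in 0:degree) for (j in 0:(degree - i))
    cols[[length(cols) + 1L]] <- xi^i * yj^j
  do.call(cbind, cols)
}

#' Flat-field correction
#'
#' Per channel, fits a 2-D polynomial of degree `flatfield_poly_degree` to
#' the median-prefiltered pre-subtraction intensities at background pixels
#' (background scales with illumination, so these trace the illumination
#' surface), normalises the fitted surface to mean one over the field and
#' divides the cube by it (epsilon-guarded). Channels with a degenerate fit
#' are skipped with a warning.
#'
#' @param cube cube after [subtract_background()].
#' @param mask the field's [mask_image()].
#' @param config a [preprocess_config()].
#' @return flattened cube with `cube$flatfield` (H x W x C array of the
#'   applied surfaces).
#' @export
flatten_field <- function(cube, mask, config = preprocess_config()) {
  check_step_order(cube, "flatten", "background")
  if (is.null(cube$presub))
    stopf("pre-subtraction data missing; run subtract_background() first")
  ebg <- eroded_background(mask)
  if (!any(ebg)) ebg <- mask$labels == 0L
  bg <- which(ebg, arr.ind = TRUE)
  d <- dim(cube$pixels)
  xi <- (bg[, 1] - 1) / max(d[1] - 1, 1)
  yj <- (bg[, 2] - 1) / max(d[2] - 1, 1)
  Xfit <- poly2d_terms(xi, yj, config$flatfield_poly_degree)
  grid <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]))
  Xall <- poly2d_terms((grid$i - 1) / max(d[1] - 1, 1),
                       (grid$j - 1) / max(d[2] - 1, 1),
                       config$flatfield_poly_degree)
  ff <- array(1, d)
  for (k in seq_len(d[3])) {
    pres <- neighbour_median_filter(cube$presub[, , k])
    y <- pres[cbind(bg[, 1], bg[, 2])]
    if (stats::sd(y) == 0 && config$flatfield_poly_degree > 0) {
      # perfectly flat background: surface is constant, nothing to correct
      next
    }
    beta <- tryCatch(qr.coef(qr(Xfit), y), error = function(e) NULL)
    if (is.null(beta) || anyNA(beta)) {
      # rank-deficient designs still give a usable least-squares surface
      # with NA coefficients for aliased terms; treat all-NA as degenerate
      if (is.null(beta) || all(is.na(beta))) {
        warnf("flat-field fit degenerate in channel %d; channel skipped", k)
        next
      }
      beta[is.na(beta)] <- 0
    }
    surf <- matrix(Xall %*% beta, d[1], d[2])
    mu <- mean(surf)
    if (!is.finite(mu) || mu <= config$epsilon) {
      warnf("flat-field surface degenerate in channel %d; channel skipped", k)
      next
    }
    surf <- surf / mu
    surf[surf < config$epsilon] <- config$epsilon
    ff[, , k] <- surf
    cube$pixels[, , k] <- cube$pixels[, , k] / surf
  }
  cube$flatfield <- ff
  cube$presub <- NULL
  cube$steps <- c(cube$steps, "flatten")
  cube
}

# 3x3 median prefilter (centre included) used before the illumination fit.
neighbour_median_filter <- function(img) {
  matrix(row_median(neighbour_stack(img, include_center = TRUE)),
         nrow(img), ncol(img))
}

# Background pixels at least `iterations` px from any cell: keeps
# cell-adjacent pixels (and soft cell skirts, whose values mix in cell
# signal) out of the illumination fit.
eroded_background <- function(mask, iterations = 4L) {
  bg <- mask$labels == 0L
  for (i in seq_len(iterations)) {
    N <- neighbour_stack(bg * 1L, include_center = TRUE)
    bg <- matrix(rowSums(N) == ncol(N), nrow(bg), ncol(bg))
  }
  bg
}

#' Spectral calibration against reference fluids
#'
#' Per channel, the gain is `calib_reference / (calib_measured -
#' water_mean)`; the cube is multiplied by it and the gains are recorded on
#' the cube (and in the sidecar on write). Reference vectors should be
#' wavelet-smoothed first (see [smooth_reference()]).
#'
#' @param cube cube after [flatten_field()].
#' @param refs a [reference_spectra()].
#' @param config a [preprocess_config()].
#' @return calibrated cube (stage `"calibrated"`).
#' @export
calibrate <- function(cube, refs, config = preprocess_config()) {
  check_step_order(cube, "calibrate", "flatten")
  d <- dim(cube$pixels)
  if (length(refs$water_mean) != d[3])
    stopf("reference spectra have %d channels, cube has %d",
          length(refs$water_mean), d[3])
  denom <- refs$calib_measured - refs$water_mean
  bad <- which(denom <= 0)
  if (length(bad))
    stopf("calibration undefined: non-positive (measured - water) in channel(s) %s",
          paste(bad - 1L, collapse = ", "))
  gains <- refs$calib_reference / denom
  for (k in seq_len(d[3])) cube$pixels[, , k] <- cube$pixels[, , k] * gains[k]
  cube$gains <- gains
  cube$steps <- c(cube$steps, "calibrate")
  advance_stage(cube, "calibrated")
}

#' Run the full preprocessing chain on one field
#'
#' Convenience wrapper: cosmic-ray removal, low-rank + wavelet denoising,
#' background subtraction, flat-field correction, and calibration, in the
#' enforced order.
#'
#' @param cube raw [spectral_cube()].
#' @param mask the field's [mask_image()].
#' @param refs [reference_spectra()] (smoothed internally).
#' @param config a [preprocess_config()].
#' @param smooth_refs smooth the reference vectors with
#'   [smooth_reference()] before calibration.
#' @return calibrated cube.
#' @export
preprocess_cube <- function(cube, mask, refs, config = preprocess_config(),
                            smooth_refs = TRUE) {
  cube <- remove_cosmic_rays(cube, config)
  cube <- denoise_lowrank(cube, config)
  cube <- subtract_background(cube, mask, config)
  cube <- flatten_field(cube, mask, config)
  if (smooth_refs)
    refs <- reference_spectra(smooth_reference(refs$water_mean),
                              smooth_reference(refs$calib_measured),
                              smooth_reference(refs$calib_reference))
  calibrate(cube, refs, config)
}
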