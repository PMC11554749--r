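# Synthetic-data generator. Per-cell 47-channel signatures are convex
# mixtures of a few endmember fluorophore spectra (NADH-, FAD-,
# lipofuscin- and collagen-like); phenotype states shift the abundances,
# replicative age follows a monotone drift with large per-cell
# heterogeneity, lines carry random spectral offsets, and rendered fields
# add flat-field, background, instrument response, Poisson + Gaussian
# noise and cosmic-ray spikes. Everything is bit-reproducible from the
# scenario seed.

band_weight <- function(peak, width, kind, center, halfwidth) {
  if (kind == "longpass") {
    1 - stats::pnorm(center, peak, width)
  } else {
    stats::pnorm(center + halfwidth, peak, width) -
      stats::pnorm(center - halfwidth, peak, width)
  }
}

#' Synthetic endmember spectra on a channel table
#'
#' Four smooth endmembers loosely shaped like the dominant cellular
#' autofluorophores (NAD(P)H: UV excitation / blue emission; FAD: blue
#' excitation / green emission; lipofuscin: broad red; collagen-like
#' matrix signal: deep-UV / violet). No photophysical accuracy is claimed;
#' they exist to give the pipeline realistic low-rank spectral structure.
#'
#' @param channels channel table (see [default_channel_table()]).
#' @return matrix `4 x n_channels`, rows named, each row max-normalised.
#' @export
endmember_spectra <- function(channels = default_channel_table()) {
  pars <- list(
    nadh       = c(ex = 351, exw = 30, em = 450, emw = 40),
    fad        = c(ex = 450, exw = 35, em = 535, emw = 45),
    lipofuscin = c(ex = 410, exw = 60, em = 600, emw = 80),
    collagen   = c(ex = 340, exw = 25, em = 420, emw = 40))
  E <- t(vapply(pars, function(p) {
    ex_w <- exp(-(channels$excitation_center_nm - p["ex"])^2 / (2 * p["exw"]^2))
    em_w <- mapply(band_weight, kind = channels$emission_kind,
                   center = channels$emission_center_or_cutoff_nm,
                   halfwidth = channels$emission_halfwidth_nm,
                   MoreArgs = list(peak = p["em"], width = p["emw"]))
    v <- ex_w * em_w
    v / max(v)
  }, numeric(nrow(channels))))
  rownames(E) <- names(pars)
  E
}

#' Build a simulation scenario
#'
#' The defaults define the study conditions every downstream test and
#' benchmark assumes: 5 donor lines arresting between 20 and 30 cumulative
#' doublings, 100 cells per observed doubling class, a monotone aging
#' drift across 28 doublings whose per-cell heterogeneity SD equals the
#' drift accumulated over 8 doublings, modest per-line spectral offsets,
#' and imaging noise (Poisson photon statistics, Gaussian read noise,
#' cosmic-ray spikes, a smooth flat-field ramp, background at ~5% of the
#' mean cell signal, and a smooth per-channel instrument response).
#'
#' @param n_lines number of donor lines.
#' @param cells_per_class cells generated per observed doubling class.
#' @param channels channel table.
#' @param base_abundance baseline endmember abundances.
#' @param state_effects named list of additive abundance shifts per
#'   phenotype state.
#' @param aging list: `drift` (abundance change over the full 28-doubling
#'   span), `amplitude` (scales the drift; 0 gives a null scenario), and
#'   `heterogeneity_sd` (`NULL` = drift accumulated over 8 doublings at
#'   amplitude 1).
#' @param line_effects_sd SD of per-line random abundance offsets.
#' @param noise list: `poisson_scale` (photons per intensity unit),
#'   `read_sd`, `cosmic_rate` (spikes per pixel-channel),
#'   `cosmic_amplitude` (`NULL` = 25 x the max endmember signal).
#' @param flat_field_amplitude peak-to-centre relative amplitude of the
#'   illumination ramp.
#' @param background_frac background level as a fraction of the mean cell
#'   signal.
#' @param morphology list: `base_radius_px`, `hypertrophy` (radius factor
#'   for senescent cells), `axis_ratio` range, `speckle_amp`,
#'   `edge_sigma_px`.
#' @param field list: `size` (pixels) and `cells_per_field`.
#' @param measurement_noise_sd relative per-feature noise on the fast-path
#'   feature table.
#' @param senescent_prob function mapping doublings-remaining to the
#'   probability of a positive senescence stain.
#' @param stro1_prob function mapping doublings-remaining to the
#'   probability of STRO-1 positivity.
#' @param seed master seed; fixes every output bit-exactly.
#' @return list of class `afmi_scenario` with all stochastic scenario
#'   constants (line offsets, instrument response, flat field) resolved.
#' @export
afmi_scenario <- function(n_lines = 5L, cells_per_class = 100L,
                          channels = default_channel_table(),
                          base_abundance = c(nadh = 1, fad = 0.6,
                                             lipofuscin = 0.2,
                                             collagen = 0.3),
                          state_effects = list(
                            senescent = c(nadh = -0.15, fad = 0.15,
                                          lipofuscin = 0.35, collagen = 0),
                            alp = c(nadh = 0.10, fad = 0.12,
                                    lipofuscin = 0, collagen = 0.15),
                            stro1 = c(nadh = 0.12, fad = -0.08,
                                      lipofuscin = 0, collagen = 0.05),
                            cycling = c(nadh = 0.20, fad = -0.05,
                                        lipofuscin = 0, collagen = 0)),
                          aging = list(drift = c(nadh = -0.35, fad = 0.25,
                                                 lipofuscin = 0.45,
                                                 collagen = 0),
                                       amplitude = 1,
                                       heterogeneity_sd = NULL),
                          line_effects_sd = 0.05,
                          noise = list(poisson_scale = 800, read_sd = 0.002,
                                       cosmic_rate = 1e-4,
                                       cosmic_amplitude = NULL),
                          flat_field_amplitude = 0.2,
                          background_frac = 0.05,
                          morphology = list(base_radius_px = 9,
                                            hypertrophy = 1.8,
                                            axis_ratio = c(0.55, 0.9),
                                            speckle_amp = 0.15,
                                            edge_sigma_px = 1.2),
                          field = list(size = 96L, cells_per_field = 5L),
                          measurement_noise_sd = 0.01,
                          senescent_prob = function(dr)
                            ifelse(dr <= 2, 0.9, 0.05),
                          stro1_prob = function(dr)
                            ifelse(dr >= 15, 0.7, 0.3),
                          seed = 1L) {
  if (line_effects_sd < 0 || measurement_noise_sd < 0)
    stopf("scenario SDs must be non-negative")
  if (is.null(aging$heterogeneity_sd))
    aging$heterogeneity_sd <- (8 / 28) * sqrt(mean(aging$drift^2))
  if (aging$heterogeneity_sd < 0) stopf("heterogeneity SD must be non-negative")
  E <- endmember_spectra(channels)
  if (is.null(noise$cosmic_amplitude))
    noise$cosmic_amplitude <- 25 * max(base_abundance %*% E)
  sc <- list(n_lines = as.integer(n_lines),
             cells_per_class = as.integer(cells_per_class),
             channels = channels, endmembers = E,
             base_abundance = base_abundance,
             state_effects = state_effects, aging = aging,
             line_effects_sd = line_effects_sd, noise = noise,
             flat_field_amplitude = flat_field_amplitude,
             background_frac = background_frac, morphology = morphology,
             field = field, measurement_noise_sd = measurement_noise_sd,
             senescent_prob = senescent_prob, stro1_prob = stro1_prob,
             seed = as.integer(seed))
  # resolve per-scenario constants deterministically from the seed
  sc$line_offsets <- with_seed(derive_seeds(seed, 1, 101L),
    matrix(stats::rnorm(n_lines * nrow(E), 0, line_effects_sd), n_lines,
           dimnames = list(NULL, rownames(E))))
  nchan <- nrow(channels)
  # smooth low-harmonic response across the channel sequence (random
  # phases/weights fixed by the seed); smoothness matters because the
  # calibration files are wavelet-smoothed downstream
  sc$instrument_response <- with_seed(derive_seeds(seed, 1, 102L), {
    t_ <- seq_len(nchan) / nchan
    ph <- stats::runif(2, 0, 2 * pi)
    w <- stats::runif(2, 0.5, 1)
    v <- w[1] * sin(2 * pi * t_ + ph[1]) + w[2] * sin(4 * pi * t_ + ph[2])
    1 + 0.18 * v / max(abs(v))
  })
  sig <- as.numeric(sc$base_abundance %*% E)
  sc$background_offsets <- background_frac * mean(sig) * (0.5 + sig / max(sig))
  class(sc) <- "afmi_scenario"
  sc
}

#' Null aging scenario
#'
#' A scenario in which cell signatures carry no information about
#' doublings remaining: zero aging drift, zero per-line offsets (lines
#' reach different doubling classes, so line-specific spectra would
#' otherwise act as an age confound), and age-independent assay
#' probabilities. Per-cell heterogeneity keeps the default (amplitude-1)
#' magnitude so the data are non-degenerate.
#'
#' @param ... overrides forwarded to [afmi_scenario()].
#' @return an `afmi_scenario`.
#' @export
null_scenario <- function(...) {
  drift <- c(nadh = -0.35, fad = 0.25, lipofuscin = 0.45, collagen = 0)
  afmi_scenario(aging = list(drift = drift, amplitude = 0,
                             heterogeneity_sd = (8 / 28) *
                               sqrt(mean(drift^2))),
                line_effects_sd = 0,
                senescent_prob = function(dr) rep(0.15, length(dr)),
                stro1_prob = function(dr) rep(0.5, length(dr)),
                ...)
}

#' @export
print.afmi_scenario <- function(x, ...) {
  cat(sprintf(paste0("<afmi_scenario> %d lines, %d cells/class, %d channels,",
                     " aging amplitude %.2g, seed %d\n"),
              x$n_lines, x$cells_per_class, nrow(x$channels),
              x$aging$amplitude, x$seed))
  invisible(x)
}

scenario_hash <- function(scenario) {
  s <- scenario
  s$senescent_prob <- deparse(s$senescent_prob)
  object_hash(s)
}

#' Simulate per-line cumulative-doubling passage logs
#'
#' Each line grows with strictly positive, decelerating per-passage
#' increments up to a line-specific arrest total drawn from \[20, 30\],
#' then records a final arrested passage with zero increment.
#'
#' @param scenario an [afmi_scenario()].
#' @return `data.frame` with `line_id`, `passage`, `cumulative_doublings`.
#' @export
simulate_passage_log <- function(scenario) {
  with_seed(derive_seeds(scenario$seed, 1, 103L), {
    out <- list()
    for (i in seq_len(scenario$n_lines)) {
      arrest <- stats::runif(1, 20, 30)
      d <- stats::runif(1, 3, 4)
      rho <- stats::runif(1, 0.82, 0.9)
      cum <- c()
      total <- 0
      while (total < arrest) {
        total <- min(total + max(d, 0.4), arrest)
        cum <- c(cum, total)
        d <- d * rho
      }
      cum <- c(cum, arrest)  # confirmed-arrest passage, zero increment
      out[[i]] <- data.frame(line_id = sprintf("L%02d", i),
                             passage = seq_along(cum),
                             cumulative_doublings = cum)
    }
    do.call(rbind, out)
  })
}

state_shift <- function(scenario, state) {
  eff <- scenario$state_effects[[state]]
  if (is.null(eff)) rep(0, nrow(scenario$endmembers)) else eff
}

#' Simulate a population of cells with ground truth
#'
#' Generates passage logs, derives the observed doubling classes, and for
#' each class draws `cells_per_class` cells (distributed over the
#' line/passage combinations that reach that class). Each cell's
#' endmember abundance vector is base + state effects + aging drift
#' x (28 - doublings_remaining)/28 + line offset + heterogeneity noise;
#' its true 47-channel signature is the abundance-weighted endmember
#' mixture, clipped at zero. Assay labels (senescence, STRO-1, ALP,
#' cycle phase with DAPI totals) are emitted consistently with the
#' spectral effects applied.
#'
#' @param scenario an [afmi_scenario()].
#' @return list with `cells` (ids, labels, geometry), `spectra`
#'   (cells x channels truth), `features` (fast-path feature table:
#'   channel means with measurement noise plus morphology), the
#'   `passage_log`, and `classes`.
#' @export
simulate_cells <- function(scenario) {
  log_df <- simulate_passage_log(scenario)
  arrest <- tapply(log_df$cumulative_doublings, log_df$line_id, max)
  log_df$label <- as.integer(round(arrest[log_df$line_id] -
                                     log_df$cumulative_doublings))
  classes <- sort(unique(log_df$label))
  E <- scenario$endmembers
  nA <- nrow(E)
  with_seed(derive_seeds(scenario$seed, 1, 104L), {
    rows <- list(); abunds <- list()
    cid <- 0L
    for (cl in classes) {
      srcs <- log_df[log_df$label == cl, ]
      pick <- srcs[rep_len(seq_len(nrow(srcs)), scenario$cells_per_class), ]
      for (r in seq_len(nrow(pick))) {
        cid <- cid + 1L
        dr <- cl
        line <- pick$line_id[r]
        line_i <- as.integer(sub("L", "", line))
        sen <- stats::runif(1) < scenario$senescent_prob(dr)
        phase <- sample(c("G1", "S", "G2"), 1, prob = c(0.7, 0.15, 0.15))
        stro <- stats::runif(1) < scenario$stro1_prob(dr)
        alp <- stats::runif(1) < 0.15
        ab <- scenario$base_abundance +
          scenario$aging$drift * scenario$aging$amplitude * (28 - dr) / 28 +
          scenario$line_offsets[line_i, ] +
          stats::rnorm(nA, 0, scenario$aging$heterogeneity_sd)
        if (sen) ab <- ab + state_shift(scenario, "senescent")
        if (stro) ab <- ab + state_shift(scenario, "stro1")
        if (alp) ab <- ab + state_shift(scenario, "alp")
        if (phase != "G1")
          ab <- ab + state_shift(scenario, "cycling") *
            ifelse(phase == "S", 0.5, 1)
        m_dapi <- 1000
        dapi <- switch(phase,
                       G1 = stats::rnorm(1, m_dapi, 0.05 * m_dapi),
                       S = stats::rnorm(1, 1.5 * m_dapi, 0.075 * m_dapi),
                       G2 = stats::rnorm(1, 2 * m_dapi, 0.1 * m_dapi))
        rad <- scenario$morphology$base_radius_px *
          ifelse(sen, scenario$morphology$hypertrophy, 1) *
          stats::runif(1, 0.85, 1.15)
        rows[[cid]] <- data.frame(
          cell_id = cid, line_id = line, passage = pick$passage[r],
          doublings_remaining = dr,
          senescent = ifelse(sen, "pos", "neg"),
          stro1 = ifelse(stro, "pos", "neg"),
          alp = ifelse(alp, "pos", "neg"),
          cycle_phase = phase, dapi_total = max(dapi, 1),
          radius_px = rad,
          axis_ratio = stats::runif(1, scenario$morphology$axis_ratio[1],
                                    scenario$morphology$axis_ratio[2]),
          angle = stats::runif(1, 0, pi))
        abunds[[cid]] <- ab
      }
    }
    cells <- do.call(rbind, rows)
    A <- do.call(rbind, abunds)
    spectra <- pmax(A %*% E, 0)
    if (any(A %*% E < 0))
      warnf("some synthetic signatures were clipped at zero")
    nchan <- ncol(spectra)
    noise_mult <- matrix(1 + stats::rnorm(length(spectra), 0,
                                          scenario$measurement_noise_sd),
                         nrow(spectra))
    feat <- as.data.frame(spectra * noise_mult)
    names(feat) <- sprintf("ch%02d_mean", seq_len(nchan) - 1L)
    feat$morph_area_um2 <- pi * cells$radius_px^2 * cells$axis_ratio
    features <- data.frame(field_id = "sim", cell_id = cells$cell_id, feat,
                           check.names = FALSE)
    list(cells = cells, spectra = spectra, features = features,
         passage_log = log_df[, c("line_id", "passage",
                                  "cumulative_doublings")],
         classes = classes)
  })
}

#' Binary channel-shift benchmark population
#'
#' The canonical classification benchmark: per-cell channel means are a
#' fixed baseline signature plus independent Gaussian channel noise, and
#' positive cells are shifted by `shift_sd` within-class SDs in
#' `n_shifted` randomly chosen channels.
#'
#' @param n cells.
#' @param n_shifted number of shifted channels.
#' @param shift_sd shift size in units of the within-class SD.
#' @param noise_sd relative within-class channel SD.
#' @param positive_frac fraction of positive cells.
#' @param scenario scenario supplying baseline signature and channels.
#' @param seed RNG seed.
#' @return list with `features`, `labels` (factor neg/pos), and the
#'   shifted channel indices.
#' @export
simulate_channel_shift <- function(n = 300L, n_shifted = 10L, shift_sd = 1,
                                   noise_sd = 0.05, positive_frac = 0.5,
                                   scenario = afmi_scenario(), seed = 1L) {
  base <- as.numeric(scenario$base_abundance %*% scenario$endmembers)
  nchan <- length(base)
  with_seed(seed, {
    shifted <- sort(sample(nchan, n_shifted))
    y <- factor(ifelse(seq_len(n) <= round(n * positive_frac), "pos", "neg"),
                levels = c("neg", "pos"))
    y <- y[sample(n)]
    sig <- noise_sd * base
    X <- matrix(stats::rnorm(n * nchan, 0, 1), n) *
      matrix(sig, n, nchan, byrow = TRUE) +
      matrix(base, n, nchan, byrow = TRUE)
    X[y == "pos", shifted] <- X[y == "pos", shifted] +
      matrix(shift_sd * sig[shifted], sum(y == "pos"), n_shifted,
             byrow = TRUE)
    feats <- as.data.frame(X)
    names(feats) <- sprintf("ch%02d_mean", seq_len(nchan) - 1L)
    list(features = feats, labels = y, shifted_channels = shifted)
  })
}

gaussian_smoother <- function(n, sigma) {
  S <- outer(seq_len(n), seq_len(n),
             function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  S / rowSums(S)
}

#' Render one field of view as a raw spectral cube plus mask
#'
#' Cells are drawn as rotated ellipses (flat interior with smooth
#' multiplicative speckle, Gaussian-softened edges; the masked profile is
#' normalised to mean one so masked channel means equal the true
#' signatures in the noise-free case). The field applies, in order:
#' background offsets, the multiplicative flat-field ramp, the per-channel
#' instrument response, Poisson and Gaussian read noise, and cosmic-ray
#' spikes. The mask records the true cell ids.
#'
#' @param cells `data.frame` rows from [simulate_cells()] (at most
#'   `field$cells_per_field`).
#' @param spectra matching rows of the true signature matrix.
#' @param scenario an [afmi_scenario()].
#' @param field_id identifier for the rendered field.
#' @param noise_on apply Poisson/read/cosmic noise.
#' @param flat_on apply the flat-field ramp.
#' @param seed RNG seed for placement, speckle and noise.
#' @return list with `cube` (raw [spectral_cube()]), `mask`
#'   ([mask_image()]), and `truth` (clean signal array, flat field,
#'   background, response, spike indices).
#' @export
render_field <- function(cells, spectra, scenario, field_id = "F01",
                         noise_on = TRUE, flat_on = TRUE, seed = 1L) {
  n <- scenario$field$size
  if (nrow(cells) > scenario$field$cells_per_field)
    stopf("at most %d cells per field", scenario$field$cells_per_field)
  nchan <- nrow(scenario$channels)
  with_seed(seed, {
    # rejection-sample non-overlapping placements; sequential placement can
    # paint itself into a corner, so restart the whole field a few times
    rads <- cells$radius_px
    centers <- NULL
    for (restart in seq_len(25L)) {
      cand <- matrix(NA_real_, nrow(cells), 2)
      placed <- TRUE
      for (i in seq_len(nrow(cells))) {
        ok <- FALSE
        for (try in seq_len(400L)) {
          p <- stats::runif(2, rads[i] + 3, n - rads[i] - 3)
          if (i == 1 || all(sqrt(colSums((t(cand[seq_len(i - 1), ,
                                                 drop = FALSE]) - p)^2)) >
                            rads[seq_len(i - 1)] + rads[i] + 2)) {
            cand[i, ] <- p; ok <- TRUE; break
          }
        }
        if (!ok) { placed <- FALSE; break }
      }
      if (placed) { centers <- cand; break }
    }
    if (is.null(centers))
      stopf("field overcrowded; reduce cells_per_field or radius")
    signal <- array(0, c(n, n, nchan))
    mask <- matrix(0L, n, n)
    for (i in seq_len(nrow(cells))) {
      a <- rads[i]; b <- rads[i] * cells$axis_ratio[i]
      th <- cells$angle[i]
      half <- ceiling(a) + 4L
      ii <- max(1, round(centers[i, 1]) - half):min(n, round(centers[i, 1]) + half)
      jj <- max(1, round(centers[i, 2]) - half):min(n, round(centers[i, 2]) + half)
      gx <- outer(ii - centers[i, 1], rep(1, length(jj)))
      gy <- outer(rep(1, length(ii)), jj - centers[i, 2])
      u <- gx * cos(th) + gy * sin(th)
      v <- -gx * sin(th) + gy * cos(th)
      rho2 <- (u / a)^2 + (v / b)^2
      inside <- rho2 <= 1
      prof <- matrix(as.numeric(inside), length(ii))
      es <- scenario$morphology$edge_sigma_px
      if (es > 0) {
        S1 <- gaussian_smoother(length(ii), es)
        S2 <- gaussian_smoother(length(jj), es)
        prof <- S1 %*% prof %*% t(S2)
      }
      spk <- matrix(stats::rnorm(length(ii) * length(jj)), length(ii))
      S1 <- gaussian_smoother(length(ii), 2)
      S2 <- gaussian_smoother(length(jj), 2)
      spk <- S1 %*% spk %*% t(S2)
      spk <- 1 + scenario$morphology$speckle_amp * spk / stats::sd(spk)
      spk[spk < 0.2] <- 0.2
      prof <- prof * spk
      # normalise so the masked mean is exactly 1
      prof <- prof / mean(prof[inside])
      for (k in seq_len(nchan))
        signal[ii, jj, k] <- signal[ii, jj, k] + prof * spectra[i, k]
      mask[ii, jj][inside] <- cells$cell_id[i]
    }
    ramp <- if (flat_on) {
      fx <- seq(-1, 1, length.out = n)
      ff <- outer(1 + scenario$flat_field_amplitude * fx * 0.8,
                  1 + scenario$flat_field_amplitude * fx * 0.6)
      ff / mean(ff)
    } else matrix(1, n, n)
    px <- array(0, c(n, n, nchan))
    for (k in seq_len(nchan))
      px[, , k] <- (signal[, , k] + scenario$background_offsets[k]) * ramp *
        scenario$instrument_response[k]
    spike_idx <- integer(0)
    if (noise_on) {
      sc <- scenario$noise$poisson_scale
      px <- array(stats::rpois(length(px), px * sc) / sc, dim(px))
      px <- px + array(stats::rnorm(length(px), 0, scenario$noise$read_sd),
                       dim(px))
      n_spk <- stats::rpois(1, scenario$noise$cosmic_rate * length(px))
      if (n_spk > 0) {
        spike_idx <- sample(length(px), n_spk)
        px[spike_idx] <- px[spike_idx] + scenario$noise$cosmic_amplitude *
          stats::runif(n_spk, 0.5, 1.5)
      }
      px[px < 0] <- 0
    }
    cube <- spectral_cube(px, channels = scenario$channels,
                          field_id = field_id, pixel_size_um = 0.5)
    list(cube = cube, mask = mask_image(mask, field_id = field_id),
         truth = list(signal = signal, flatfield = ramp,
                      background = scenario$background_offsets,
                      response = scenario$instrument_response,
                      spike_index = spike_idx, centers = centers))
  })
}

#' Simulate calibration reference spectra
#'
#' The spectrofluorometer truth is a smooth positive spectrum across the
#' channel sequence; the imaged calibration fluid is that truth
#' passed through the scenario's instrument response plus the water blank
#' (and optional measurement noise). The true per-channel gains
#' (1/response) are returned for recovery checks.
#'
#' @param scenario an [afmi_scenario()].
#' @param noise_sd relative measurement noise on the imaged spectra.
#' @param seed RNG seed (used only when `noise_sd > 0`).
#' @return list with `refs` (a [reference_spectra()]) and `gains_truth`.
#' @export
simulate_references <- function(scenario, noise_sd = 0, seed = 1L) {
  nchan <- nrow(scenario$channels)
  # smooth positive spectrum across the channel sequence (the reference
  # fluid is chosen so its recorded spectrum varies slowly from channel
  # to channel, matching the smoothness the wavelet step assumes)
  t_ <- seq_len(nchan) / nchan
  ref <- 1.2 + 0.6 * sin(2 * pi * t_ + 0.7) + 0.25 * cos(4 * pi * t_)
  resp <- scenario$instrument_response
  water <- 0.02 * mean(ref) * (1 + 0.3 * sin(seq_len(length(ref)) / 5))
  measured <- ref * resp + water
  if (noise_sd > 0)
    measured <- with_seed(seed, measured *
                            (1 + stats::rnorm(length(ref), 0, noise_sd)))
  list(refs = reference_spectra(water, measured, ref),
       gains_truth = 1 / resp)
}
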