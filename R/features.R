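# Per-cell feature extraction: intensity statistics, GLCM texture,
# morphology, assay gating, and table assembly with the correlation filter.

#' Feature-extraction configuration
#'
#' @param families feature families to extract.
#' @param ratio_channels 0-based channel ids whose pairwise mean ratios are
#'   emitted as `ratio` features.
#' @param glcm_levels grey levels for texture quantisation (per cell, over
#'   its own min--max).
#' @param glcm_offsets list of (di, dj) pixel offsets, averaged.
#' @param epsilon guard for ratio denominators.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(families = c("intensity", "texture",
                                        "morphology", "ratio"),
                           ratio_channels = c(2L, 10L, 20L, 33L, 42L),
                           glcm_levels = 16L,
                           glcm_offsets = list(c(0L, 1L), c(1L, 0L),
                                               c(1L, 1L), c(1L, -1L)),
                           epsilon = 1e-9) {
  structure(list(families = families,
                 ratio_channels = as.integer(ratio_channels),
                 glcm_levels = as.integer(glcm_levels),
                 glcm_offsets = glcm_offsets, epsilon = epsilon),
            class = "feature_config")
}

.intensity_stats <- c("mean", "median", "sd", "skew", "kurt", "p10", "p90")
.texture_stats <- c("contrast", "correlation", "energy", "homogeneity",
                    "entropy")
.morph_names <- c("morph_area_um2", "morph_perimeter_um",
                  "morph_equiv_diameter_um", "morph_major_axis_um",
                  "morph_minor_axis_um", "morph_eccentricity",
                  "morph_solidity", "morph_extent", "morph_circularity")

#' Feature catalog
#'
#' Enumerates every feature the configured extraction produces, in column
#' order: name, family, channels involved, and a definition id. The
#' catalog is reproducible from the configuration alone and fully
#' determines feature-table column order.
#'
#' @param config a [feature_config()].
#' @param n_channels number of spectral channels.
#' @return `data.frame` with columns `name`, `family`, `channels`,
#'   `definition`.
#' @export
feature_catalog <- function(config = feature_config(), n_channels = 47L) {
  rows <- list()
  ch <- seq_len(n_channels) - 1L
  if ("intensity" %in% config$families)
    for (s in .intensity_stats)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("ch%02d_%s", ch, s), family = "intensity",
        channels = as.character(ch), definition = paste0("masked_", s))
  if ("texture" %in% config$families)
    for (s in .texture_stats)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("ch%02d_glcm_%s", ch, s), family = "texture",
        channels = as.character(ch), definition = paste0("glcm16_", s))
  if ("morphology" %in% config$families)
    rows[[length(rows) + 1L]] <- data.frame(
      name = .morph_names, family = "morphology", channels = "",
      definition = sub("^morph_", "", .morph_names))
  if ("ratio" %in% config$families && length(config$ratio_channels) > 1) {
    pr <- utils::combn(sort(config$ratio_channels), 2)
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("ratio_ch%02d_ch%02d", pr[1, ], pr[2, ]),
      family = "ratio",
      channels = sprintf("%d,%d", pr[1, ], pr[2, ]),
      definition = "mean_ratio")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

cell_pixels <- function(cube, mask, cell_id) {
  sel <- mask$labels == cell_id
  if (!any(sel)) stopf("cell %s has an empty mask in field '%s'",
                       cell_id, mask$field_id)
  sel
}

sample_skewness <- function(x) {
  n <- length(x); s <- stats::sd(x)
  if (n < 3 || !is.finite(s) || s == 0) return(0)
  m <- mean(x)
  (sum((x - m)^3) / n) / (sqrt(sum((x - m)^2) / n))^3
}

excess_kurtosis <- function(x) {
  n <- length(x); s <- stats::sd(x)
  if (n < 4 || !is.finite(s) || s == 0) return(0)
  m <- mean(x)
  (sum((x - m)^4) / n) / (sum((x - m)^2) / n)^2 - 3
}

#' Intensity features of one cell
#'
#' Per channel: mean, median, SD (n-1 denominator), sample skewness,
#' excess kurtosis, and 10th/90th percentiles of the masked pixels
#' (7 x n_channels features), plus pairwise channel-mean ratios for the
#' configured channel subset. Zero-SD cells have skewness and kurtosis 0
#' by convention.
#'
#' @param cube calibrated [spectral_cube()].
#' @param mask [mask_image()] on the cube's grid.
#' @param cell_id cell label in the mask.
#' @param config a [feature_config()].
#' @return named numeric vector.
#' @export
extract_intensity_features <- function(cube, mask, cell_id,
                                       config = feature_config()) {
  if (cube$stage != "calibrated")
    stopf("intensity features require a calibrated cube (stage is '%s')",
          cube$stage)
  sel <- cell_pixels(cube, mask, cell_id)
  nc <- dim(cube$pixels)[3]
  out <- numeric(0)
  means <- numeric(nc)
  for (k in seq_len(nc)) {
    v <- cube$pixels[, , k][sel]
    means[k] <- mean(v)
    s <- if (length(v) > 1) stats::sd(v) else 0
    q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
    vals <- c(means[k], stats::median(v), s, sample_skewness(v),
              excess_kurtosis(v), q[1], q[2])
    names(vals) <- sprintf("ch%02d_%s", k - 1L, .intensity_stats)
    out <- c(out, vals)
  }
  if ("ratio" %in% config$families && length(config$ratio_channels) > 1) {
    pr <- utils::combn(sort(config$ratio_channels), 2)
    r <- means[pr[1, ] + 1L] / (means[pr[2, ] + 1L] + config$epsilon)
    names(r) <- sprintf("ratio_ch%02d_ch%02d", pr[1, ], pr[2, ])
    out <- c(out, r)
  }
  out
}

# Symmetric normalised GLCM of one quantised plane restricted to the mask,
# averaged over offsets.
glcm_matrix <- function(q, sel, levels, offsets) {
  P <- matrix(0, levels, levels)
  n_used <- 0L
  r <- nrow(q); cc <- ncol(q)
  for (off in offsets) {
    di <- off[1]; dj <- off[2]
    i1 <- max(1, 1 - di):min(r, r - di)
    j1 <- max(1, 1 - dj):min(cc, cc - dj)
    if (!length(i1) || !length(j1)) next
    a <- q[i1, j1, drop = FALSE]
    b <- q[i1 + di, j1 + dj, drop = FALSE]
    ok <- sel[i1, j1, drop = FALSE] & sel[i1 + di, j1 + dj, drop = FALSE]
    if (!any(ok)) next
    tab <- table(factor(a[ok], levels = seq_len(levels)),
                 factor(b[ok], levels = seq_len(levels)))
    G <- unclass(tab) + t(unclass(tab))  # symmetric
    P <- P + G / sum(G)
    n_used <- n_used + 1L
  }
  if (n_used == 0L) return(NULL)
  P / n_used
}

glcm_stats <- function(P) {
  lv <- seq_len(nrow(P))
  pi_ <- rowSums(P); pj <- colSums(P)
  mui <- sum(lv * pi_); muj <- sum(lv * pj)
  si <- sqrt(sum((lv - mui)^2 * pi_)); sj <- sqrt(sum((lv - muj)^2 * pj))
  I <- matrix(lv, nrow(P), ncol(P)); J <- t(I)
  contrast <- sum(P * (I - J)^2)
  correlation <- if (si > 0 && sj > 0)
    sum(P * (I - mui) * (J - muj)) / (si * sj) else 0
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(I - J)))
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' GLCM texture features of one cell
#'
#' Per channel, a grey-level co-occurrence matrix over the cell's masked
#' pixels (quantised to `glcm_levels` levels over the cell's own min--max,
#' configured offsets averaged, symmetric, normalised) summarised as
#' contrast, correlation, energy, homogeneity and entropy (natural log).
#' A single-grey-level cell yields the degenerate conventions contrast 0,
#' correlation 0, energy 1, homogeneity 1, entropy 0.
#'
#' @inheritParams extract_intensity_features
#' @return named numeric vector (5 x n_channels values).
#' @export
extract_texture_features <- function(cube, mask, cell_id,
                                     config = feature_config()) {
  sel <- cell_pixels(cube, mask, cell_id)
  idx <- which(sel, arr.ind = TRUE)
  if (diff(range(idx[, 1])) < 2 || diff(range(idx[, 2])) < 2)
    stopf("cell %s bounding box is smaller than 3x3 pixels", cell_id)
  nc <- dim(cube$pixels)[3]
  out <- numeric(0)
  for (k in seq_len(nc)) {
    img <- cube$pixels[, , k]
    v <- img[sel]
    rng <- range(v)
    q <- matrix(1L, nrow(img), ncol(img))
    if (diff(rng) > 0) {
      qv <- 1L + pmin(config$glcm_levels - 1L,
                      floor((img - rng[1]) / diff(rng) * config$glcm_levels))
      q <- matrix(as.integer(qv), nrow(img))
    }
    P <- glcm_matrix(q, sel, config$glcm_levels, config$glcm_offsets)
    st <- if (is.null(P)) c(contrast = 0, correlation = 0, energy = 1,
                            homogeneity = 1, entropy = 0) else glcm_stats(P)
    if (diff(rng) == 0)
      st <- c(contrast = 0, correlation = 0, energy = 1, homogeneity = 1,
              entropy = 0)
    names(st) <- sprintf("ch%02d_glcm_%s", k - 1L, .texture_stats)
    out <- c(out, st)
  }
  out
}

#' Morphology features of one cell
#'
#' Area, perimeter (8-connected contour chain length), equivalent
#' diameter, major/minor axis lengths (4 sqrt of the covariance
#' eigenvalues, matching the standard ellipse-of-inertia convention),
#' eccentricity, solidity (area over convex hull of the pixel corners),
#' extent (area over bounding box) and circularity 4*pi*A/P^2.
#'
#' @param mask [mask_image()].
#' @param cell_id cell label in the mask.
#' @param pixel_size_um physical pixel size in micrometres.
#' @return named numeric vector of length 9.
#' @export
extract_morphology_features <- function(mask, cell_id, pixel_size_um = 1) {
  sel <- mask$labels == cell_id
  if (!any(sel)) stopf("cell %s has an empty mask", cell_id)
  ps <- pixel_size_um %||% 1
  idx <- which(sel, arr.ind = TRUE)
  npx <- nrow(idx)
  area <- npx * ps^2
  # contour chain perimeter on a padded crop
  r1 <- range(idx[, 1]); r2 <- range(idx[, 2])
  crop <- matrix(0, diff(r1) + 3L, diff(r2) + 3L)
  crop[cbind(idx[, 1] - r1[1] + 2L, idx[, 2] - r2[1] + 2L)] <- 1
  per_px <- tryCatch({
    oc <- EBImage::ocontour(crop)[[1]]
    if (nrow(oc) < 2) 4 else {
      d <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
      sum(sqrt(rowSums(d^2)))
    }
  }, error = function(e) 4 * sqrt(npx))
  # second moments of the pixel-centre cloud
  cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
  m20 <- mean((idx[, 1] - cx)^2); m02 <- mean((idx[, 2] - cy)^2)
  m11 <- mean((idx[, 1] - cx) * (idx[, 2] - cy))
  ev <- eigen(matrix(c(m20, m11, m11, m02), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  major <- 4 * sqrt(ev[1]); minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  # convex hull over pixel corners
  corners <- rbind(cbind(idx[, 1] - 0.5, idx[, 2] - 0.5),
                   cbind(idx[, 1] - 0.5, idx[, 2] + 0.5),
                   cbind(idx[, 1] + 0.5, idx[, 2] - 0.5),
                   cbind(idx[, 1] + 0.5, idx[, 2] + 0.5))
  h <- grDevices::chull(corners)
  hp <- corners[h, , drop = FALSE]
  hull_area <- abs(sum(hp[, 1] * c(hp[-1, 2], hp[1, 2]) -
                       hp[, 2] * c(hp[-1, 1], hp[1, 1]))) / 2
  solidity <- if (hull_area > 0) min(npx / hull_area, 1) else 1
  extent <- npx / ((diff(r1) + 1) * (diff(r2) + 1))
  circ <- if (per_px > 0) 4 * pi * npx / per_px^2 else 0
  out <- c(area, per_px * ps, 2 * sqrt(npx / pi) * ps, major * ps,
           minor * ps, ecc, solidity, extent, circ)
  names(out) <- .morph_names
  out
}

#' Gate cells into cell-cycle phases from total DNA stain intensity
#'
#' Locates the G1 mode of the total-DAPI distribution as the global kernel
#' density peak m and applies configurable multiplier thresholds:
#' totals <= 1.25 m are G1, (1.25 m, 1.75 m] are S, above 1.75 m are G2.
#' M is never assigned automatically (mitotic cells need an explicit
#' override label).
#'
#' @param dapi_totals per-cell positive totals.
#' @param thresholds multipliers on the G1 mode for the G1/S and S/G2
#'   boundaries.
#' @param g1_mode optional user-supplied mode, used as a fallback when the
#'   density estimate fails.
#' @return factor with levels `G1`, `S`, `G2`, `M`.
#' @export
gate_dna_content <- function(dapi_totals, thresholds = c(1.25, 1.75),
                             g1_mode = NULL) {
  if (any(dapi_totals <= 0)) stopf("DAPI totals must be positive")
  if (length(dapi_totals) < 30)
    warnf("fewer than 30 cells; DNA-content gating may be unreliable")
  m <- tryCatch({
    d <- stats::density(dapi_totals)
    d$x[which.max(d$y)]
  }, error = function(e) NULL)
  if (is.null(m) || !is.finite(m) || m <= 0) {
    if (is.null(g1_mode))
      stopf("could not locate the G1 mode; supply g1_mode")
    warnf("density peak not found; using the supplied G1 mode")
    m <- g1_mode
  }
  phase <- ifelse(dapi_totals <= thresholds[1] * m, "G1",
                  ifelse(dapi_totals <= thresholds[2] * m, "S", "G2"))
  factor(phase, levels = c("G1", "S", "G2", "M"))
}

#' Gate stain positivity from background- and area-normalised totals
#'
#' The per-cell score is `(total - background * area) / area`; a cell is
#' positive when its score exceeds the threshold, which is either an
#' absolute value or (default) the Otsu split of the score distribution.
#'
#' @param stain_totals per-cell integrated stain intensity.
#' @param background background intensity per unit area (scalar or
#'   per-cell).
#' @param areas per-cell areas (positive).
#' @param threshold_rule `list(method = "otsu")` or
#'   `list(method = "absolute", value = t)`.
#' @return factor `pos`/`neg` with attributes `score` and `threshold`.
#' @export
gate_stain_positivity <- function(stain_totals, background, areas,
                                  threshold_rule = list(method = "otsu")) {
  if (any(areas <= 0)) stopf("cell areas must be positive")
  if (any(background < 0)) stopf("background must be non-negative")
  score <- (stain_totals - background * areas) / areas
  thr <- switch(threshold_rule$method,
    absolute = threshold_rule$value,
    otsu = otsu_threshold(score),
    stopf("unknown threshold method '%s'", threshold_rule$method))
  if (is.na(thr)) {
    warnf("degenerate score distribution; all cells called negative")
    call <- rep("neg", length(score))
  } else {
    call <- ifelse(score > thr, "pos", "neg")
  }
  structure(factor(call, levels = c("neg", "pos")),
            score = score, threshold = thr)
}

#' Extract all features for every cell in one field
#'
#' @param cube calibrated [spectral_cube()].
#' @param mask [mask_image()].
#' @param config a [feature_config()].
#' @return `data.frame`: `field_id`, `cell_id`, then one column per
#'   catalog feature.
#' @export
extract_cell_features <- function(cube, mask, config = feature_config()) {
  ids <- mask_cell_ids(mask)
  cat <- feature_catalog(config, dim(cube$pixels)[3])
  rows <- lapply(ids, function(id) {
    v <- numeric(0)
    if ("intensity" %in% config$families || "ratio" %in% config$families)
      v <- c(v, extract_intensity_features(cube, mask, id, config))
    if ("texture" %in% config$families)
      v <- c(v, extract_texture_features(cube, mask, id, config))
    if ("morphology" %in% config$families)
      v <- c(v, extract_morphology_features(mask, id, cube$pixel_size_um %||% 1))
    v[cat$name[cat$name %in% names(v)]]
  })
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(field_id = cube$field_id, cell_id = ids, out,
             check.names = FALSE)
}

#' Join features with labels and apply the correlation filter
#'
#' Joins per-cell feature rows with assay labels on `(field_id, cell_id)`,
#' drops rows with any non-finite feature value (count reported via
#' message), and removes one member of every feature pair with absolute
#' Pearson correlation above `cor_threshold`, keeping the higher-variance
#' member (variance ties keep the lexicographically smaller name). The
#' scan order is the catalog column order, so the result is deterministic.
#'
#' @param features `data.frame` from [extract_cell_features()] (or rbind
#'   of several fields).
#' @param labels optional label `data.frame` (see [read_labels()]).
#' @param cor_threshold absolute-correlation cutoff.
#' @return filtered, joined `data.frame`; dropped feature names in
#'   `attr(, "dropped_features")`, dropped row count in
#'   `attr(, "dropped_cells")`.
#' @export
clean_and_assemble <- function(features, labels = NULL, cor_threshold = 0.95) {
  id_cols <- c("field_id", "cell_id")
  if (!all(id_cols %in% names(features)))
    stopf("features must carry field_id and cell_id columns")
  if (anyDuplicated(features[id_cols]))
    stopf("join key collision: duplicated (field_id, cell_id) in features")
  if (!is.null(labels)) {
    if (anyDuplicated(labels[id_cols]))
      stopf("join key collision: duplicated (field_id, cell_id) in labels")
    features <- merge(features, labels, by = id_cols, all.x = TRUE,
                      sort = FALSE)
  }
  feat_cols <- setdiff(names(features)[vapply(features, is.numeric,
                                              logical(1))],
                       c(id_cols, "passage", "doublings_remaining",
                         "dapi_total"))
  fin <- rowSums(!is.finite(as.matrix(features[feat_cols]))) == 0
  n_drop <- sum(!fin)
  if (n_drop > 0) {
    message(sprintf("clean_and_assemble: dropped %d cell(s) with non-finite values",
                    n_drop))
    features <- features[fin, , drop = FALSE]
  }
  X <- as.matrix(features[feat_cols])
  v <- apply(X, 2, stats::var)
  C <- suppressWarnings(stats::cor(X))
  keep <- rep(TRUE, length(feat_cols))
  names(keep) <- feat_cols
  for (i in seq_along(feat_cols)) {
    if (!keep[i]) next
    for (j in seq_along(feat_cols)) {
      if (j <= i || !keep[j]) next
      r <- C[i, j]
      if (is.finite(r) && abs(r) > cor_threshold) {
        if (v[i] > v[j]) keep[j] <- FALSE
        else if (v[j] > v[i]) { keep[i] <- FALSE; break }
        else {  # variance tie: keep the lexicographically smaller name
          if (feat_cols[i] < feat_cols[j]) keep[j] <- FALSE
          else { keep[i] <- FALSE; break }
        }
      }
    }
  }
  dropped <- feat_cols[!keep]
  out <- features[, c(setdiff(names(features), dropped)), drop = FALSE]
  attr(out, "dropped_features") <- dropped
  attr(out, "dropped_cells") <- n_drop
  out
}
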