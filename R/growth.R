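# Remaining-population-doublings prediction: integer doubling-class
# labels, per-class half-sample withholding, coarse k-nearest-neighbour
# prediction in the full LD space (closest-average-distance single-label
# rule), 30-repeat median aggregate scoring, RMSPE/MAE, the k-sweep, and
# unsupervised age clustering.

#' Derive per-cell doublings-remaining labels from passage logs
#'
#' The label of a cell imaged at cumulative doubling level c, from a line
#' whose log ends at arrest level T, is `round(T - c)`. Cells of the same
#' line and passage share a label.
#'
#' @param cells `data.frame` with `line_id` and `passage` per cell.
#' @param passage_log `data.frame` with `line_id`, `passage`,
#'   `cumulative_doublings`; each line's final row is its arrest level.
#' @return integer vector of doubling labels, one per cell row.
#' @export
make_doubling_labels <- function(cells, passage_log) {
  labs <- integer(nrow(cells))
  for (ln in unique(cells$line_id)) {
    log_i <- passage_log[passage_log$line_id == ln, ]
    if (!nrow(log_i)) stopf("no passage log for line '%s'", ln)
    log_i <- log_i[order(log_i$passage), ]
    arrest <- log_i$cumulative_doublings[nrow(log_i)]  # log ends at arrest
    sel <- cells$line_id == ln
    cum <- log_i$cumulative_doublings[match(cells$passage[sel], log_i$passage)]
    if (anyNA(cum))
      stopf("line '%s': cells imaged at passages missing from the log", ln)
    rem <- arrest - cum
    if (any(rem < -0.5))
      stopf("line '%s': cumulative doublings exceed the arrest level", ln)
    labs[sel] <- as.integer(round(pmax(rem, 0)))
  }
  labs
}

#' Withhold half of one doubling class
#'
#' @param idx indices of the cells of one class.
#' @param seed RNG seed.
#' @return list with `test` (floor(n/2) withheld indices) and `train`.
#' @export
split_half_sample <- function(idx, seed = 1L) {
  n <- length(idx)
  if (n < 2) {
    warnf("class of size %d: withholding 0 cells", n)
    return(list(test = integer(0), train = idx))
  }
  test <- with_seed(seed, sample(idx, n %/% 2L))
  list(test = sort(test), train = sort(setdiff(idx, test)))
}

#' Coarse k-nearest-neighbour label prediction
#'
#' For each test point, its k nearest training points (Euclidean distance
#' in the full LD space) are partitioned by label; the predicted label is
#' the one whose members lie at the smallest mean distance from the test
#' point. Ties break towards the label with more members among the k,
#' then towards the smaller label value.
#'
#' @param train_coords numeric matrix of training LD coordinates.
#' @param train_labels numeric labels per training row.
#' @param test_coords numeric matrix of test LD coordinates.
#' @param k neighbourhood size (capped at the training size).
#' @return numeric vector of predicted labels.
#' @export
coarse_knn_predict <- function(train_coords, train_labels, test_coords,
                               k = 400L) {
  Xtr <- as.matrix(train_coords); Xte <- as.matrix(test_coords)
  if (nrow(Xtr) == 0) stopf("empty training set")
  lab <- as.numeric(train_labels)
  k <- min(k, nrow(Xtr))
  # squared cross-distances via the expansion ||a-b||^2 = a2 + b2 - 2ab
  a2 <- rowSums(Xte^2); b2 <- rowSums(Xtr^2)
  G <- Xte %*% t(Xtr)
  out <- numeric(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    d2 <- b2 - 2 * G[i, ] + a2[i]
    nn <- order(d2)[seq_len(k)]
    dd <- sqrt(pmax(d2[nn], 0))
    ll <- lab[nn]
    md <- tapply(dd, ll, mean)
    cn <- tapply(dd, ll, length)
    labs_present <- as.numeric(names(md))
    best <- which(md == min(md))
    if (length(best) > 1) {                 # mean-distance tie
      best <- best[cn[best] == max(cn[best])]
      if (length(best) > 1) best <- best[which.min(labs_present[best])]
    }
    out[i] <- labs_present[best[1]]
  }
  out
}

#' Aggregate score of a withheld test sample
#'
#' Median of the per-cell predicted labels; the mean of the central two
#' values for even counts, so half-integers can occur.
#'
#' @param predictions numeric predicted labels (non-empty).
#' @return numeric scalar.
#' @export
aggregate_score <- function(predictions) {
  if (!length(predictions)) stopf("no predictions to aggregate")
  stats::median(predictions)
}

# One repeat: split every class in half, fit the embedding on the retained
# cells, project the withheld cells, coarse-KNN predict.  Returns enough
# state for the k-sweep to reuse the fitted geometry across k values.
doublings_repeat <- function(X, labels, n_select, pca_var_retained, seed) {
  classes <- sort(unique(labels))
  seeds <- derive_seeds(seed, length(classes), stream = 3L)
  test_idx <- integer(0)
  for (ci in seq_along(classes)) {
    idx <- which(labels == classes[ci])
    sp <- split_half_sample(idx, seeds[ci])
    test_idx <- c(test_idx, sp$test)
  }
  train_idx <- setdiff(seq_along(labels), test_idx)
  emb <- fit_embedding(X[train_idx, , drop = FALSE], labels[train_idx],
                       n_select = n_select,
                       pca_var_retained = pca_var_retained)
  list(emb = emb, train_idx = train_idx, test_idx = test_idx,
       train_coords = emb$train_coords,
       test_coords = predict(emb, X[test_idx, , drop = FALSE]),
       classes = classes)
}

#' Evaluate doublings-remaining prediction
#'
#' For each of `repeats` randomisations: withhold half of every doubling
#' class, fit the z-score / MRMR (top `n_select`) / PCA / LDA embedding on
#' the retained cells only, project the withheld cells, predict each with
#' the coarse KNN, and record the per-class aggregate (median) score.
#' Reports, per class, the mean aggregate over repeats with an empirical
#' 95% prediction interval (2.5/97.5 percentiles), plus RMSPE and MAE of
#' the mean aggregates against the true values.
#'
#' @param table feature table.
#' @param labels integer doublings-remaining per cell (>= 3 classes).
#' @param k KNN neighbourhood size.
#' @param repeats number of randomised repeats.
#' @param seed RNG seed.
#' @param n_select MRMR features (capped at the feature count).
#' @param pca_var_retained PCA variance retained.
#' @return an object of class `doublings_report`.
#' @export
evaluate_doublings <- function(table, labels, k = 400L, repeats = 30L,
                               seed = 1L, n_select = 100L,
                               pca_var_retained = 0.99) {
  X <- as_feature_matrix(table)
  labels <- as.numeric(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 3) stopf("need at least 3 doubling classes")
  rep_seeds <- derive_seeds(seed, repeats, stream = 7L)
  agg <- matrix(NA_real_, repeats, length(classes),
                dimnames = list(NULL, classes))
  for (r in seq_len(repeats)) {
    st <- doublings_repeat(X, labels, n_select, pca_var_retained,
                           rep_seeds[r])
    pred <- coarse_knn_predict(st$train_coords, labels[st$train_idx],
                               st$test_coords, k)
    te_lab <- labels[st$test_idx]
    for (ci in seq_along(classes)) {
      sel <- te_lab == classes[ci]
      if (any(sel)) agg[r, ci] <- aggregate_score(pred[sel])
    }
  }
  summarise_doublings(agg, classes, k, repeats, seed)
}

summarise_doublings <- function(agg, classes, k, repeats, seed) {
  mean_agg <- colMeans(agg, na.rm = TRUE)
  lo <- apply(agg, 2, stats::quantile, 0.025, na.rm = TRUE)
  hi <- apply(agg, 2, stats::quantile, 0.975, na.rm = TRUE)
  err <- mean_agg - classes
  structure(list(
    per_class = data.frame(true = classes, mean_aggregate = mean_agg,
                           pi_lower = lo, pi_upper = hi,
                           row.names = NULL),
    rmspe = sqrt(mean(err^2)), mae = mean(abs(err)),
    spearman = suppressWarnings(stats::cor(mean_agg, classes,
                                           method = "spearman")),
    k = k, repeats = repeats, seed = seed,
    aggregates = agg), class = "doublings_report")
}

#' @export
print.doublings_report <- function(x, ...) {
  cat(sprintf("<doublings_report> k=%d, %d repeats, %d classes\n",
              x$k, x$repeats, nrow(x$per_class)))
  cat(sprintf("  RMSPE %.3f   MAE %.3f   Spearman rho %.3f\n",
              x$rmspe, x$mae, x$spearman))
  invisible(x)
}

#' RMSPE as a function of the KNN neighbourhood size
#'
#' Evaluates the doublings predictor over a grid of k values with shared
#' per-repeat splits and embeddings (results are identical to calling
#' [evaluate_doublings()] once per k with the same seed).
#'
#' @inheritParams evaluate_doublings
#' @param k_grid neighbourhood sizes to test.
#' @return list with `curve` (`data.frame` k, rmspe, mae), `best_k`, and
#'   the per-k reports.
#' @export
sweep_k <- function(table, labels, k_grid = c(25L, 50L, 100L, 200L, 300L,
                                              400L, 500L, 600L),
                    repeats = 30L, seed = 1L, n_select = 100L,
                    pca_var_retained = 0.99) {
  if (!length(k_grid)) stopf("k_grid must be non-empty")
  X <- as_feature_matrix(table)
  labels <- as.numeric(labels)
  classes <- sort(unique(labels))
  k_grid <- sort(unique(as.integer(k_grid)))
  rep_seeds <- derive_seeds(seed, repeats, stream = 7L)
  aggs <- lapply(k_grid, function(k)
    matrix(NA_real_, repeats, length(classes), dimnames = list(NULL, classes)))
  names(aggs) <- as.character(k_grid)
  for (r in seq_len(repeats)) {
    st <- doublings_repeat(X, labels, n_select, pca_var_retained,
                           rep_seeds[r])
    te_lab <- labels[st$test_idx]
    for (kk in seq_along(k_grid)) {
      pred <- coarse_knn_predict(st$train_coords, labels[st$train_idx],
                                 st$test_coords, k_grid[kk])
      for (ci in seq_along(classes)) {
        sel <- te_lab == classes[ci]
        if (any(sel)) aggs[[kk]][r, ci] <- aggregate_score(pred[sel])
      }
    }
  }
  reports <- lapply(seq_along(k_grid), function(kk)
    summarise_doublings(aggs[[kk]], classes, k_grid[kk], repeats, seed))
  curve <- data.frame(k = k_grid,
                      rmspe = vapply(reports, `[[`, numeric(1), "rmspe"),
                      mae = vapply(reports, `[[`, numeric(1), "mae"))
  list(curve = curve, best_k = k_grid[which.min(curve$rmspe)],
       reports = stats::setNames(reports, k_grid))
}

#' Unsupervised age clustering in LD space
#'
#' K-means (10 seeded restarts, best inertia) on the first two LD
#' components; clusters are reported in order of decreasing mean
#' doublings-remaining, with a label histogram per cluster.
#'
#' @param embedding_coords LD coordinate matrix.
#' @param labels per-cell doubling labels.
#' @param n_clusters number of clusters.
#' @param seed RNG seed.
#' @param use_dims columns of the coordinate matrix to cluster on.
#' @return list with `assignments` (1 = oldest-labelled... ordered by
#'   descending mean label), `cluster_means`, and `histograms`.
#' @export
cluster_ages <- function(embedding_coords, labels, n_clusters = 3L,
                         seed = 1L, use_dims = 1:2) {
  C <- as.matrix(embedding_coords)
  use_dims <- use_dims[use_dims <= ncol(C)]
  C <- C[, use_dims, drop = FALSE]
  if (nrow(C) < n_clusters) stopf("fewer points than clusters")
  km <- with_seed(seed, stats::kmeans(C, centers = n_clusters, nstart = 10L,
                                      iter.max = 100L))
  labels <- as.numeric(labels)
  means <- tapply(labels, km$cluster, mean)
  ord <- order(-means)  # 1 = oldest mean doublings-remaining... descending
  remap <- integer(n_clusters); remap[ord] <- seq_len(n_clusters)
  assign <- remap[km$cluster]
  hist_list <- lapply(seq_len(n_clusters), function(cl)
    table(labels[assign == cl]))
  list(assignments = assign,
       cluster_means = as.numeric(means[ord]),
       histograms = hist_list, n_clusters = n_clusters)
}
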