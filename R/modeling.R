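# Classification stack: z-scoring, MRMR (MIQ) selection, PCA followed by a
# regularised linear discriminant embedding, ADASYN/down-sampling, SVM and
# LDA classifiers, cross-validated ROC analysis, and the Kruskal-Wallis
# line-heterogeneity check.

as_feature_matrix <- function(table) {
  if (is.matrix(table)) {
    storage.mode(table) <- "double"
    if (is.null(colnames(table)))
      colnames(table) <- sprintf("f%04d", seq_len(ncol(table)))
    return(table)
  }
  num <- vapply(table, is.numeric, logical(1))
  as.matrix(table[, num, drop = FALSE])
}

#' Fit z-scoring on a training table and apply it to both tables
#'
#' Training-set means and SDs only; zero-SD features are dropped with a
#' warning.
#'
#' @param train_table,test_table numeric feature tables (matrix or
#'   data.frame); `test_table` may be `NULL`.
#' @return list with scaled `train`, `test`, and the stored `mean`, `sd`,
#'   `kept` names.
#' @export
zscore_fit_apply <- function(train_table, test_table = NULL) {
  X <- as_feature_matrix(train_table)
  mu <- colMeans(X)
  sd_ <- apply(X, 2, stats::sd)
  kept <- sd_ > 0
  if (!all(kept))
    warnf("dropping %d zero-variance feature(s): %s", sum(!kept),
          paste(utils::head(colnames(X)[!kept], 5), collapse = ", "))
  X <- X[, kept, drop = FALSE]
  mu <- mu[kept]; sd_ <- sd_[kept]
  scale_fun <- function(M) sweep(sweep(M[, names(mu), drop = FALSE], 2, mu),
                                 2, sd_, "/")
  out_test <- if (!is.null(test_table))
    scale_fun(as_feature_matrix(test_table)) else NULL
  list(train = scale_fun(X), test = out_test, mean = mu, sd = sd_,
       kept = names(mu))
}

# Equal-frequency discretisation into at most n_bins bins. Variables with
# n_bins or fewer distinct values are already discrete and are used as-is
# (quantile breaks would merge distinct values into one bin).
bin_equal_freq <- function(x, n_bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= n_bins) return(factor(x, levels = sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1L),
                               names = FALSE, type = 7))
  if (length(br) < 2L) return(factor(rep(1L, length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

# Mutual information (nats) between two discrete variables.
mi_discrete <- function(fx, fy) {
  tab <- table(fx, fy)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

mi_binned <- function(x, y_factor, n_bins = 10L) {
  mi_discrete(bin_equal_freq(x, n_bins), y_factor)
}

#' Minimum-redundancy maximum-relevance feature ranking (MIQ)
#'
#' Greedy forward selection. Relevance V(f) is the mutual information
#' between the feature (discretised into `n_bins` equal-frequency bins)
#' and the class; redundancy W(f|S) is the mean mutual information between
#' f and the already-selected features under the same binning. The first
#' pick maximises V; every later pick maximises the quotient
#' V / (W + 1e-12). Ties break towards the lexicographically smaller
#' feature name, making the ranking fully deterministic.
#'
#' @param table feature table (matrix or data.frame of numerics).
#' @param labels class labels (coerced to factor; at least 2 classes).
#' @param n_select number of features to rank (at most the feature count).
#' @param n_bins discretisation bins.
#' @return `data.frame` with `name`, `relevance` and the greedy selection
#'   `score`, in selection order.
#' @export
mrmr_rank <- function(table, labels, n_select, n_bins = 10L) {
  X <- as_feature_matrix(table)
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("MRMR needs at least 2 classes")
  p <- ncol(X)
  if (n_select > p)
    stopf("n_select (%d) exceeds the number of features (%d)", n_select, p)
  eps <- 1e-12
  bins <- lapply(seq_len(p), function(j) bin_equal_freq(X[, j], n_bins))
  V <- vapply(bins, function(b) mi_discrete(b, y), numeric(1))
  names(V) <- colnames(X)
  pick_best <- function(score, cand) {
    mx <- max(score[cand])
    ties <- cand[score[cand] >= mx - .Machine$double.eps * max(1, abs(mx))]
    ties[order(colnames(X)[ties])][1]
  }
  cand <- seq_len(p)
  first <- pick_best(V, cand)
  sel <- first
  scores <- V[first]
  Wsum <- rep(0, p)  # running sum of MI(feature, selected)
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(p), sel)
    last <- sel[length(sel)]
    for (j in cand) Wsum[j] <- Wsum[j] + mi_discrete(bins[[j]], bins[[last]])
    crit <- rep(-Inf, p)
    crit[cand] <- V[cand] / (Wsum[cand] / length(sel) + eps)
    nxt <- pick_best(crit, cand)
    sel <- c(sel, nxt)
    scores <- c(scores, crit[nxt])
  }
  data.frame(name = colnames(X)[sel], relevance = unname(V[sel]),
             score = unname(scores))
}

# Regularised Fisher discriminant projection in a whitened basis.
lda_projection <- function(X, y, reg = 1e-6) {
  y <- factor(y)
  p <- ncol(X); g <- nlevels(y)
  mu <- colMeans(X)
  Sw <- matrix(0, p, p); Sb <- matrix(0, p, p)
  for (cl in levels(y)) {
    Xi <- X[y == cl, , drop = FALSE]
    mc <- colMeans(Xi)
    Xc <- sweep(Xi, 2, mc)
    Sw <- Sw + crossprod(Xc)
    Sb <- Sb + nrow(Xi) * tcrossprod(mc - mu)
  }
  Swr <- Sw + reg * sum(diag(Sw)) * diag(p)
  es <- eigen(Swr, symmetric = TRUE)
  if (any(es$values <= 0))
    stopf("within-class scatter is singular despite regularisation")
  half_inv <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
  M <- half_inv %*% Sb %*% half_inv
  ee <- eigen((M + t(M)) / 2, symmetric = TRUE)
  m <- min(g - 1L, p)
  W <- half_inv %*% ee$vectors[, seq_len(m), drop = FALSE]
  for (j in seq_len(m)) {  # deterministic sign: dominant loading positive
    i <- which.max(abs(W[, j]))
    if (W[i, j] < 0) W[, j] <- -W[, j]
  }
  list(W = W, eigenvalues = ee$values[seq_len(m)], classes = levels(y))
}

#' Fit the z-score / MRMR / PCA / LDA embedding
#'
#' The full dimensionality-reduction pipeline: z-scoring (training
#' statistics), MRMR selection of the top `n_select` features, PCA
#' retaining `pca_var_retained` of the variance, and a linear discriminant
#' projection to `n_classes - 1` dimensions with the within-class scatter
#' regularised by `+1e-6 tr(Sw) I`. The fitted model is a pure function of
#' its parameters: [predict.afmi_embedding()] reproduces the stored
#' training coordinates exactly.
#'
#' @param train_table feature table.
#' @param labels class labels.
#' @param n_select MRMR features to keep (capped at the feature count).
#' @param pca_var_retained fraction of variance the PCA step retains.
#' @return an object of class `afmi_embedding`.
#' @export
fit_embedding <- function(train_table, labels, n_select = 50L,
                          pca_var_retained = 0.99) {
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  zs <- zscore_fit_apply(train_table)
  X <- zs$train
  if (nrow(X) <= nlevels(y))
    stopf("need more training rows than classes")
  n_sel <- min(n_select, ncol(X))
  rk <- mrmr_rank(X, y, n_sel)
  Xs <- X[, rk$name, drop = FALSE]
  pc <- stats::prcomp(Xs, center = TRUE, scale. = FALSE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  m <- max(which(cum >= pca_var_retained)[1], 1L)
  m <- min(m, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(m), drop = FALSE]
  scores <- pc$x[, seq_len(m), drop = FALSE]
  ld <- lda_projection(scores, y)
  model <- structure(list(
    kept_features = zs$kept, zscore_mean = zs$mean, zscore_sd = zs$sd,
    mrmr_ranking = rk, n_selected = n_sel,
    pca_center = pc$center, pca_rotation = rot, pca_retained = m,
    lda_projection = ld$W, lda_eigenvalues = ld$eigenvalues,
    class_list = levels(y)), class = "afmi_embedding")
  model$train_coords <- predict(model, train_table)
  model$train_labels <- y
  model
}

#' Project new data into the fitted LD space
#' @param object an [fit_embedding()] model.
#' @param newdata feature table carrying (at least) the model's features.
#' @param ... unused.
#' @return numeric matrix, one row per cell, `n_classes - 1` columns.
#' @export
predict.afmi_embedding <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)
  miss <- setdiff(object$kept_features, colnames(X))
  if (length(miss)) stopf("newdata lacks feature(s): %s",
                          paste(utils::head(miss, 5), collapse = ", "))
  X <- X[, object$kept_features, drop = FALSE]
  X <- sweep(sweep(X, 2, object$zscore_mean), 2, object$zscore_sd, "/")
  X <- X[, object$mrmr_ranking$name, drop = FALSE]
  S <- sweep(X, 2, object$pca_center) %*% object$pca_rotation
  coords <- S %*% object$lda_projection
  colnames(coords) <- sprintf("LD%d", seq_len(ncol(coords)))
  coords
}

#' @export
print.afmi_embedding <- function(x, ...) {
  cat(sprintf(paste0("<afmi_embedding> %d features -> MRMR %d -> PCA %d ",
                     "-> %d LD dims (%d classes)\n"),
              length(x$kept_features), x$n_selected, x$pca_retained,
              ncol(x$lda_projection), length(x$class_list)))
  invisible(x)
}

#' Classifier specification
#'
#' @param kind `"linear_svm"`, `"polynomial_svm"` or `"lda"`.
#' @param svm_cost SVM cost parameter.
#' @param poly_degree polynomial kernel degree (polynomial SVM only).
#' @param class_weighting `"none"` or `"balanced"` (class imbalance is
#'   normally handled by resampling instead).
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("linear_svm", "polynomial_svm", "lda"),
                            svm_cost = 1, poly_degree = 3L,
                            class_weighting = c("none", "balanced")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, svm_cost = svm_cost,
                 poly_degree = as.integer(poly_degree),
                 class_weighting = match.arg(class_weighting)),
            class = "classifier_spec")
}

train_classifier <- function(spec, X, y) {
  y <- factor(y)
  wts <- if (spec$class_weighting == "balanced") {
    w <- length(y) / (nlevels(y) * table(y)); as.numeric(w)
  } else NULL
  if (spec$kind == "lda") {
    list(kind = "lda", fit = MASS::lda(X, grouping = y))
  } else {
    kern <- if (spec$kind == "linear_svm") "linear" else "polynomial"
    cw <- if (is.null(wts)) NULL else stats::setNames(wts, levels(y))
    fit <- e1071::svm(x = X, y = y, kernel = kern, cost = spec$svm_cost,
                      degree = spec$poly_degree, scale = FALSE,
                      class.weights = cw)
    list(kind = "svm", fit = fit)
  }
}

# Continuous decision score oriented so larger = more `positive`.
score_classifier <- function(model, X, positive) {
  if (model$kind == "lda") {
    pr <- predict(model$fit, X)
    as.numeric(pr$posterior[, positive])
  } else {
    pred <- predict(model$fit, X, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    lab <- colnames(dv)[1]
    first <- strsplit(lab, "/")[[1]][1]
    s <- dv[, 1]
    if (first == positive) as.numeric(s) else -as.numeric(s)
  }
}

# AUC with a fixed orientation (never auto-flipped above 0.5).
auc_fixed <- function(y, score, positive) {
  y <- factor(y)
  neg <- setdiff(levels(y), positive)
  r <- pROC::roc(response = y, predictor = score,
                 levels = c(neg, positive), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' ADASYN minority up-sampling
#'
#' For each minority point the density ratio r_i is the fraction of
#' majority points among its `k_density` nearest neighbours (all classes);
#' the G = N_maj - N_min synthetic points are allocated proportionally to
#' the normalised r (largest-remainder rounding so the allocation sums to
#' G exactly) and drawn as convex combinations x_i + U(0,1) (x_z - x_i)
#' with x_z a random one of x_i's `k_density` nearest minority
#' neighbours. When no minority point has a majority neighbour the
#' allocation falls back to uniform with a warning.
#'
#' @param train_coords numeric matrix (e.g. LD coordinates).
#' @param labels binary labels.
#' @param k_density neighbourhood size.
#' @param seed RNG seed.
#' @return list with augmented `coords`, `labels`, and `n_synthetic`.
#' @export
adasyn_upsample <- function(train_coords, labels, k_density = 5L, seed = 1L) {
  X <- as.matrix(train_coords)
  y <- factor(labels)
  if (nlevels(y) != 2) stopf("ADASYN requires binary labels")
  cnt <- table(y)
  minority <- names(cnt)[which.min(cnt)]
  G <- as.integer(abs(diff(as.numeric(cnt))))
  if (G == 0L)
    return(list(coords = X, labels = y, n_synthetic = 0L))
  min_idx <- which(y == minority)
  if (length(min_idx) < k_density + 1L)
    stopf("minority class needs at least k_density + 1 = %d members",
          k_density + 1L)
  D <- as.matrix(stats::dist(X))
  r <- vapply(min_idx, function(i) {
    nb <- order(D[i, -i])  # indices into the vector without i
    others <- seq_len(nrow(X))[-i]
    kn <- others[nb[seq_len(k_density)]]
    mean(y[kn] != minority)
  }, numeric(1))
  if (sum(r) == 0) {
    warnf("no borderline minority points; uniform ADASYN allocation")
    r <- rep(1, length(r))
  }
  rhat <- r / sum(r)
  g <- floor(rhat * G)
  rem <- G - sum(g)
  if (rem > 0) {
    frac <- rhat * G - g
    g[order(-frac, seq_along(frac))[seq_len(rem)]] <-
      g[order(-frac, seq_along(frac))[seq_len(rem)]] + 1L
  }
  Dmin <- D[min_idx, min_idx, drop = FALSE]
  synth <- with_seed(seed, {
    out <- matrix(0, 0, ncol(X))
    for (ii in seq_along(min_idx)) {
      if (g[ii] == 0) next
      i <- min_idx[ii]
      o <- order(Dmin[ii, -ii])[seq_len(k_density)]
      o <- o + (o >= ii)  # map back to positions including ii
      nbm <- min_idx[o]
      z <- sample(nbm, g[ii], replace = TRUE)
      lam <- stats::runif(g[ii])
      out <- rbind(out, X[rep(i, g[ii]), , drop = FALSE] +
                     lam * (X[z, , drop = FALSE] - X[rep(i, g[ii]), , drop = FALSE]))
    }
    out
  })
  list(coords = rbind(X, synth),
       labels = factor(c(as.character(y), rep(minority, nrow(synth))),
                       levels = levels(y)),
       n_synthetic = nrow(synth))
}

#' Random down-sampling of the majority class
#'
#' @param labels binary labels.
#' @param seed RNG seed.
#' @return sorted integer indices of the retained rows (all minority plus
#'   a uniform random majority subset of equal size).
#' @export
downsample_majority <- function(labels, seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) != 2) stopf("down-sampling requires binary labels")
  cnt <- table(y)
  minority <- names(cnt)[which.min(cnt)]
  majority <- setdiff(levels(y), minority)
  if (cnt[minority] == cnt[majority]) return(seq_along(y))
  maj_idx <- which(y == majority)
  keep <- with_seed(seed, sample(maj_idx, cnt[[minority]]))
  sort(c(which(y == minority), keep))
}

#' Cross-validated evaluation of one classification endpoint
#'
#' Stratified k-fold cross-validation with strict test-fold isolation:
#' scaling, MRMR, PCA, LDA and any resampling are fitted on the training
#' fold only. Each fold reports the ROC AUC of the continuous decision
#' values plus sensitivity and specificity at the fold's Youden-optimal
#' threshold.
#'
#' @param table feature table.
#' @param labels binary labels.
#' @param classifier a [classifier_spec()].
#' @param embedding list with `n_select` and `pca_var_retained`.
#' @param resample `"none"`, `"adasyn"` or `"downsample"` (training folds
#'   only).
#' @param n_folds number of folds (each class needs at least `n_folds`
#'   members).
#' @param seed RNG seed controlling folds and resampling.
#' @param positive label of the positive class (defaults to the second
#'   factor level).
#' @return an object of class `evaluation_report`.
#' @export
crossvalidate <- function(table, labels, classifier = classifier_spec(),
                          embedding = list(n_select = 50L,
                                           pca_var_retained = 0.99),
                          resample = c("none", "adasyn", "downsample"),
                          n_folds = 5L, seed = 1L, positive = NULL) {
  resample <- match.arg(resample)
  X <- as_feature_matrix(table)
  y <- factor(labels)
  if (nlevels(y) != 2) stopf("crossvalidate expects binary labels")
  if (is.null(positive)) positive <- levels(y)[2]
  cnt <- table(y)
  small <- names(cnt)[cnt < n_folds]
  if (length(small))
    stopf("class '%s' has fewer members (%d) than folds (%d)",
          small[1], cnt[[small[1]]], n_folds)
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      f[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    f
  })
  sub_seeds <- derive_seeds(seed, n_folds, stream = 11L)
  per_fold <- list(); pooled_scores <- numeric(0); pooled_y <- character(0)
  for (k in seq_len(n_folds)) {
    tr <- folds != k; te <- !tr
    emb <- fit_embedding(X[tr, , drop = FALSE], y[tr],
                         n_select = embedding$n_select,
                         pca_var_retained = embedding$pca_var_retained %||% 0.99)
    ctr <- emb$train_coords; ytr <- y[tr]
    if (resample == "adasyn") {
      up <- adasyn_upsample(ctr, ytr, seed = sub_seeds[k])
      ctr <- up$coords; ytr <- up$labels
    } else if (resample == "downsample") {
      keep <- downsample_majority(ytr, seed = sub_seeds[k])
      ctr <- ctr[keep, , drop = FALSE]; ytr <- ytr[keep]
    }
    mdl <- train_classifier(classifier, ctr, ytr)
    cte <- predict(emb, X[te, , drop = FALSE])
    sc <- score_classifier(mdl, cte, positive)
    neg <- setdiff(levels(y), positive)
    r <- pROC::roc(response = y[te], predictor = sc,
                   levels = c(neg, positive), direction = "<", quiet = TRUE)
    best <- pROC::coords(r, "best", best.method = "youden",
                         ret = c("threshold", "sensitivity", "specificity"),
                         transpose = FALSE)
    per_fold[[k]] <- data.frame(fold = k, auc = as.numeric(pROC::auc(r)),
                                sensitivity = best$sensitivity[1],
                                specificity = best$specificity[1],
                                threshold = best$threshold[1])
    pooled_scores <- c(pooled_scores, sc)
    pooled_y <- c(pooled_y, as.character(y[te]))
  }
  folds_df <- do.call(rbind, per_fold)
  neg <- setdiff(levels(y), positive)
  pr <- pROC::roc(response = factor(pooled_y, levels = levels(y)),
                  predictor = pooled_scores, levels = c(neg, positive),
                  direction = "<", quiet = TRUE)
  pooled_best <- pROC::coords(pr, "best", best.method = "youden",
                              transpose = FALSE)
  thr <- pooled_best$threshold[1]
  pred <- ifelse(pooled_scores > thr, positive, neg)
  confusion <- table(truth = factor(pooled_y, levels = levels(y)),
                     predicted = factor(pred, levels = levels(y)))
  structure(list(
    folds = folds_df,
    auc_mean = mean(folds_df$auc), auc_sd = stats::sd(folds_df$auc),
    sensitivity_mean = mean(folds_df$sensitivity),
    sensitivity_sd = stats::sd(folds_df$sensitivity),
    specificity_mean = mean(folds_df$specificity),
    specificity_sd = stats::sd(folds_df$specificity),
    roc_points = data.frame(fpr = 1 - pr$specificities,
                            tpr = pr$sensitivities),
    confusion = confusion, n_per_class = as.list(table(y)),
    classifier = classifier$kind, resample = resample,
    n_folds = n_folds, positive = positive, seed = seed),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s (%s resampling), %d folds\n",
              x$classifier, x$resample, x$n_folds))
  cat(sprintf("  AUC  %.3f +/- %.3f\n", x$auc_mean, x$auc_sd))
  cat(sprintf("  sens %.3f +/- %.3f   spec %.3f +/- %.3f  (Youden)\n",
              x$sensitivity_mean, x$sensitivity_sd,
              x$specificity_mean, x$specificity_sd))
  invisible(x)
}

#' Kruskal-Wallis test of per-line channel differences
#'
#' For every channel-mean feature, tests whether its distribution differs
#' across cell lines (Kruskal-Wallis), adjusts the p-values by
#' Benjamini-Hochberg, and reports the fraction of channels significant at
#' `alpha`.
#'
#' @param table table of channel-mean features (one column per channel).
#' @param line_ids per-cell line identifiers (>= 2 lines, >= 3 cells
#'   each).
#' @param alpha BH significance level.
#' @return list with `p_values`, `p_adjusted`, `significant` (names) and
#'   `fraction_significant`.
#' @export
line_heterogeneity <- function(table, line_ids, alpha = 0.05) {
  X <- as_feature_matrix(table)
  line <- factor(line_ids)
  if (nlevels(line) < 2) stopf("need at least 2 lines")
  if (any(table(line) < 3)) stopf("every line needs at least 3 cells")
  p <- apply(X, 2, function(v) stats::kruskal.test(v, line)$p.value)
  padj <- stats::p.adjust(p, method = "BH")
  sig <- names(padj)[padj < alpha]
  list(p_values = p, p_adjusted = padj, significant = sig,
       fraction_significant = length(sig) / ncol(X))
}
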