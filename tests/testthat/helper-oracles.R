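# Independent oracles used by the acceptance and module tests. These are
# deliberately naive re-implementations (plain loops, closed forms) kept
# separate from the package's code paths.

# Brute-force closest-average-distance KNN rule.
oracle_coarse_knn <- function(train, labels, test, k) {
  labels <- as.numeric(labels)
  apply(test, 1, function(x) {
    d <- sqrt(colSums((t(train) - x)^2))
    o <- order(d)[seq_len(min(k, nrow(train)))]
    dd <- d[o]; ll <- labels[o]
    md <- tapply(dd, ll, mean)
    cn <- table(ll)[names(md)]
    cand <- names(md)[md == min(md)]
    if (length(cand) > 1) {
      cand <- cand[cn[cand] == max(cn[cand])]
      cand <- cand[which.min(as.numeric(cand))]
    }
    as.numeric(cand[1])
  })
}

# Step-by-step exhaustive evaluation of the MIQ criterion (own MI code via
# the entropy identity, own equal-frequency binning).
oracle_mrmr <- function(X, y, n_sel, n_bins = 10L) {
  bin10 <- function(x) {
    if (length(unique(x)) <= n_bins) return(factor(x))  # already discrete
    br <- unique(stats::quantile(x, seq(0, 1, length.out = n_bins + 1),
                                 names = FALSE))
    if (length(br) < 2) return(factor(rep(1L, length(x))))
    cut(x, br, include.lowest = TRUE)
  }
  ent <- function(f) {
    p <- table(f) / length(f); p <- p[p > 0]
    -sum(p * log(p))
  }
  mi <- function(a, b) ent(a) + ent(b) - ent(interaction(a, b, drop = FALSE))
  bins <- lapply(seq_len(ncol(X)), function(j) bin10(X[, j]))
  V <- vapply(bins, function(b) mi(b, y), numeric(1))
  sel <- integer(0); cand <- seq_len(ncol(X))
  while (length(sel) < n_sel) {
    crit <- vapply(cand, function(j) {
      if (!length(sel)) V[j]
      else V[j] / (mean(vapply(sel, function(s) mi(bins[[j]], bins[[s]]),
                               numeric(1))) + 1e-12)
    }, numeric(1))
    mx <- max(crit)
    ties <- cand[crit >= mx - 1e-14 * max(1, abs(mx))]
    pick <- ties[order(colnames(X)[ties])][1]
    sel <- c(sel, pick); cand <- setdiff(cand, pick)
  }
  colnames(X)[sel]
}

# Mann-Whitney rank statistic AUC.
oracle_auc <- function(y, score, positive) {
  pos <- y == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Two separable Gaussian blobs for classifier tests.
make_blobs <- function(n = 60, p = 4, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n * p), n), matrix(rnorm(n * p, sep), n))
  colnames(X) <- sprintf("f%02d", seq_len(p))
  list(X = X, y = factor(rep(c("neg", "pos"), each = n),
                         levels = c("neg", "pos")))
}

# Angle in degrees between two directions (sign-agnostic).
direction_angle <- function(a, b) {
  acos(min(1, abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2)))) * 180 / pi
}

# Small rendered field with everything known, reused by preprocess tests.
render_test_field <- function(seed = 3L, noise_on = FALSE, n_cells = 4L) {
  sc <- afmi_scenario(cells_per_class = 4L, seed = seed)
  sim <- suppressWarnings(simulate_cells(sc))
  idx <- seq_len(n_cells)
  rf <- render_field(sim$cells[idx, ], sim$spectra[idx, , drop = FALSE],
                     sc, noise_on = noise_on, seed = seed + 1L)
  list(scenario = sc, sim = sim, rf = rf)
}
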