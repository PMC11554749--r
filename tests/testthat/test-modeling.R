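test_that("z-scoring uses training statistics only", {
  set.seed(1)
  X <- matrix(rnorm(200, 5, 2), 50); colnames(X) <- paste0("f", 1:4)
  zs <- zscore_fit_apply(X, X)
  expect_equal(unname(colMeans(zs$test)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(zs$test, 2, sd)), rep(1, 4), tolerance = 1e-12)

  shifted <- X + 10
  zs2 <- zscore_fit_apply(X, shifted)
  expect_equal(zs2$test, zs$test + rep(10 / zs$sd, each = nrow(X)),
               tolerance = 1e-10)

  Xc <- cbind(X, const = 1)
  expect_warning(z3 <- zscore_fit_apply(Xc), "zero-variance")
  expect_false("const" %in% z3$kept)
})

test_that("MRMR puts a label-copy first and penalises redundant copies", {
  set.seed(2)
  n <- 120
  y <- factor(sample(0:1, n, TRUE))
  yn <- as.numeric(as.character(y))
  # a perfect label copy always ranks first on relevance alone
  Xp <- cbind(lab = yn, a = rnorm(n), b = rnorm(n))
  expect_equal(mrmr_rank(Xp, y, 3L)$name[1], "lab")

  # an exact duplicate of the top feature is displaced by a weaker but
  # non-redundant informative feature (the quotient penalises W)
  strong <- yn + rnorm(n, 0, 0.3)
  X <- cbind(strong = strong, strong_copy = strong,
             weak = yn + rnorm(n, 0, 1.2), noise = rnorm(n))
  rk <- mrmr_rank(X, y, 4L)
  expect_equal(rk$name[1], "strong")
  expect_false(rk$name[2] == "strong_copy")
  expect_setequal(rk$name, colnames(X))
  expect_error(mrmr_rank(X, y, 5L), "exceeds")
  expect_error(mrmr_rank(X, factor(rep("a", n)), 2L), "2 classes")
})

test_that("MRMR greedy choice matches exhaustive evaluation on small problems", {
  set.seed(3)
  for (i in 1:5) {
    p <- sample(3:6, 1); n <- 100
    X <- matrix(rnorm(n * p), n); colnames(X) <- sprintf("v%02d", seq_len(p))
    y <- factor(sample(0:2, n, TRUE))
    X[, 1] <- X[, 1] + as.numeric(as.character(y))
    expect_identical(mrmr_rank(X, y, p)$name, oracle_mrmr(X, y, p))
  }
})

test_that("the fitted embedding is a pure function and separates separable classes", {
  b <- make_blobs(n = 80, p = 5, sep = 4, seed = 4)
  emb <- fit_embedding(b$X, b$y, n_select = 5L)
  c1 <- predict(emb, b$X)
  expect_equal(c1, emb$train_coords, tolerance = 1e-10)
  expect_equal(predict(emb, b$X), c1)  # deterministic

  # Fisher criterion collapses under label permutation
  fisher <- function(coords, y) {
    m <- tapply(coords[, 1], y, mean)
    v <- tapply(coords[, 1], y, var)
    (diff(m))^2 / mean(v)
  }
  set.seed(5)
  yperm <- sample(b$y)
  emb_p <- fit_embedding(b$X, yperm, n_select = 5L)
  expect_gt(fisher(emb$train_coords, b$y),
            fisher(emb_p$train_coords, yperm))
  expect_error(fit_embedding(b$X[c(1, 81), ], b$y[c(1, 81)]),
               "more training rows")
})

test_that("two-class embedding direction equals the pooled-covariance closed form", {
  set.seed(6)
  p <- 6; n <- 400
  Sig <- 0.4^abs(outer(1:p, 1:p, "-"))
  X <- matrix(rnorm(n * p), n) %*% chol(Sig)
  y <- factor(rep(c("a", "b"), each = n / 2))
  mu <- rnorm(p)
  X[y == "b", ] <- sweep(X[y == "b", ], 2, mu / sqrt(sum(mu^2)) * 2, "+")
  colnames(X) <- sprintf("f%02d", 1:p)
  emb <- fit_embedding(X, y, n_select = p, pca_var_retained = 0.9999)
  D <- diag(1 / emb$zscore_sd)
  Pm <- matrix(0, p, p)
  Pm[cbind(match(emb$mrmr_ranking$name, emb$kept_features), 1:p)] <- 1
  w <- D %*% Pm %*% emb$pca_rotation %*% emb$lda_projection
  Xa <- X[y == "a", ]; Xb <- X[y == "b", ]
  Sp <- (crossprod(sweep(Xa, 2, colMeans(Xa))) +
         crossprod(sweep(Xb, 2, colMeans(Xb)))) / (n - 2)
  w_ref <- solve(Sp, colMeans(Xb) - colMeans(Xa))
  expect_lt(direction_angle(w, w_ref), 0.5)
  # independent cross-check against MASS::lda on the raw features
  w_mass <- MASS::lda(X, y)$scaling[, 1]
  expect_lt(direction_angle(w, w_mass), 0.5)
})

test_that("ADASYN balances counts with synthetic points on minority segments", {
  set.seed(7)
  X <- rbind(matrix(rnorm(160), 80, 2), matrix(rnorm(50, 2.5), 25, 2))
  y <- factor(rep(c("neg", "pos"), c(80, 25)))
  up <- adasyn_upsample(X, y, k_density = 5L, seed = 11L)
  cnt <- table(up$labels)
  expect_lte(abs(cnt[["neg"]] - cnt[["pos"]]), 5L)
  expect_equal(up$n_synthetic, 55L)
  # every synthetic point is a convex combination of two minority points
  minpts <- X[y == "pos", ]
  synth <- up$coords[-seq_len(nrow(X)), , drop = FALSE]
  on_segment <- vapply(seq_len(nrow(synth)), function(s) {
    z <- synth[s, ]
    ok <- FALSE
    for (i in seq_len(nrow(minpts))) {
      for (j in seq_len(nrow(minpts))) {
        d <- minpts[j, ] - minpts[i, ]
        if (sum(d^2) == 0) next
        lam <- sum((z - minpts[i, ]) * d) / sum(d^2)
        if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
            sqrt(sum((minpts[i, ] + lam * d - z)^2)) < 1e-9) { ok <- TRUE; break }
      }
      if (ok) break
    }
    ok
  }, logical(1))
  expect_true(all(on_segment))

  balanced <- adasyn_upsample(X[1:50, ], factor(rep(c("neg", "pos"), 25)),
                              seed = 1L)
  expect_equal(balanced$n_synthetic, 0L)
  # same seed reproduces, different seed differs
  up2 <- adasyn_upsample(X, y, seed = 11L)
  expect_equal(up$coords, up2$coords)
})

test_that("majority down-sampling equalises counts", {
  y <- factor(rep(c("neg", "pos"), c(100, 40)))
  idx <- downsample_majority(y, seed = 3L)
  expect_equal(as.integer(table(y[idx])), c(40L, 40L))
  expect_identical(downsample_majority(factor(rep(c("a", "b"), 10))), 1:20)
  idx2 <- downsample_majority(y, seed = 4L)
  expect_false(identical(idx, idx2))
  expect_equal(length(idx2), length(idx))
})

test_that("cross-validation is perfect on separable data and chance after shuffling", {
  b <- make_blobs(n = 50, p = 4, sep = 8, seed = 8)
  rep1 <- crossvalidate(b$X, b$y, classifier_spec("linear_svm"), seed = 2L)
  expect_equal(rep1$auc_mean, 1.0)
  expect_equal(rep1$auc_sd, 0.0)
  expect_true(all(rep1$folds$auc == 1))

  set.seed(9)
  big <- make_blobs(n = 150, p = 4, sep = 0.0, seed = 9)  # pure noise
  rep0 <- crossvalidate(big$X, big$y, classifier_spec("linear_svm"), seed = 2L)
  expect_gt(rep0$auc_mean, 0.35)
  expect_lt(rep0$auc_mean, 0.65)

  expect_error(crossvalidate(b$X[1:52, ], factor(rep(c("a", "b"), c(50, 2))),
                             n_folds = 5L), "fewer members")
})

test_that("fold AUC equals the Mann-Whitney statistic for every classifier kind", {
  b <- make_blobs(n = 40, p = 3, sep = 1.2, seed = 10)
  for (kind in c("linear_svm", "polynomial_svm", "lda")) {
    set.seed(11)
    emb <- fit_embedding(b$X, b$y, n_select = 3L)
    mdl <- afmicell:::train_classifier(classifier_spec(kind),
                                       emb$train_coords, b$y)
    sc <- afmicell:::score_classifier(mdl, emb$train_coords, "pos")
    expect_equal(afmicell:::auc_fixed(b$y, sc, "pos"),
                 oracle_auc(b$y, sc, "pos"), tolerance = 1e-12)
  }
})

test_that("line heterogeneity flags shifted channels and respects the null", {
  set.seed(12)
  n_per <- 50
  base <- matrix(rnorm(3 * n_per * 47), 3 * n_per, 47)
  colnames(base) <- sprintf("ch%02d_mean", 0:46)
  lines <- rep(c("L1", "L2", "L3"), each = n_per)
  shifted <- base
  shifted[lines == "L3", 1:20] <- shifted[lines == "L3", 1:20] + 3
  res <- line_heterogeneity(shifted, lines)
  expect_true(all(sprintf("ch%02d_mean", 0:19) %in% res$significant))
  expect_gte(res$fraction_significant, 20 / 47)

  null <- line_heterogeneity(base, lines)
  expect_lte(null$fraction_significant, 0.15)

  expect_error(line_heterogeneity(base, rep("L1", nrow(base))), "2 lines")
  expect_error(line_heterogeneity(base[1:7, ], c(rep("L1", 5), "L2", "L2")),
               "3 cells")
})
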