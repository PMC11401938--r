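test_that("stratified folds are balanced, disjoint, exhaustive, and seeded", {
  labels <- rep(c(0L, 1L), each = 10)
  folds <- stratified_kfold(labels, 10, seed = 5)
  for (f in folds) {
    expect_identical(length(f$test), 2L)
    expect_identical(sum(labels[f$test]), 1L)  # exactly 1 case + 1 control
  }
  tests <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_identical(tests, 1:20)                 # partition
  expect_identical(stratified_kfold(labels, 10, seed = 5), folds)
  expect_false(identical(stratified_kfold(labels, 10, seed = 6), folds))
  expect_error(stratified_kfold(c(0, 0, 0, 1), 3, 1), "fewer")
})

test_that("fold class ratios stay within one subject of the global ratio", {
  withr::with_seed(8, {
    labels <- sample(c(rep(0L, 33), rep(1L, 21)))
  })
  k <- 5
  folds <- stratified_kfold(labels, k, seed = 2)
  for (f in folds) {
    n_case <- sum(labels[f$test])
    expect_lte(abs(n_case - 21 / k), 1)
  }
})

test_that("metrics reproduce hand-computed confusion counts", {
  # TP=3 FN=1 TN=2 FP=2 at cutoff 0.5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  s <- c(0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.9, 0.55)
  m <- compute_metrics(y, s, 0.5)
  expect_identical(m$sen, 0.75)
  expect_identical(m$spe, 0.5)
  expect_identical(m$acc, 0.625)
  # perfect separation regardless of calibration
  m2 <- compute_metrics(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_identical(unlist(m2[c("acc", "auc", "sen", "spe")], use.names = FALSE),
                   rep(1, 4))
  expect_error(compute_metrics(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is the rank statistic: tie-robust and monotone-invariant", {
  y <- c(0, 0, 1, 1, 0, 1)
  s <- c(0.1, 0.5, 0.5, 0.9, 0.3, 0.7)
  auc <- compute_metrics(y, s)$auc
  # ties between a case and a control count 1/2
  expect_equal(auc, (3 + 3 + 0.5 + 2) / 9, tolerance = 1e-12)
  expect_equal(compute_metrics(y, exp(s))$auc, auc, tolerance = 1e-12)
  expect_equal(compute_metrics(y, 5 * s - 2)$auc, auc, tolerance = 1e-12)
  # independent route: pROC on an untied example
  y2 <- rep(c(0, 1), 10)
  withr::with_seed(3, s2 <- runif(20) + 0.3 * y2)
  expect_equal(compute_metrics(y2, s2)$auc,
               as.numeric(pROC::auc(pROC::roc(y2, s2, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("the Welch test matches the hand-evaluated formula and conventions", {
  a <- c(0.8, 0.82, 0.84); b <- c(0.7, 0.72, 0.74)
  tt <- two_sample_t_test(a, b)
  se <- sqrt(stats::var(a) / 3 + stats::var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((stats::var(a) / 3)^2 / 2 + (stats::var(b) / 3)^2 / 2)
  expect_equal(tt$t, t_hand, tolerance = 1e-6)
  expect_equal(tt$p, 2 * stats::pt(-abs(t_hand), df_hand), tolerance = 1e-6)
  # identical samples: no evidence of difference
  expect_identical(two_sample_t_test(c(1, 2, 3), c(3, 2, 1))$t, 0)
  expect_equal(two_sample_t_test(c(1, 2, 3), c(2, 1, 3))$p, 1, tolerance = 1e-12)
  # degenerate zero-variance convention
  expect_identical(two_sample_t_test(c(1, 1), c(1, 1)), tibble::tibble(t = 0, p = 1))
  expect_identical(two_sample_t_test(c(1, 1), c(2, 2))$p, 0)
})

test_that("silhouette matches a brute-force pairwise computation", {
  withr::with_seed(9, {
    X <- rbind(matrix(rnorm(8, mean = 0), 4, 2), matrix(rnorm(6, mean = 3), 3, 2))
  })
  lab <- c(1, 1, 1, 1, 2, 2, 2)
  # independent per-point oracle
  D <- as.matrix(dist(X))
  s_hand <- vapply(1:7, function(i) {
    own <- which(lab == lab[i] & seq_len(7) != i)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(cl) mean(D[i, lab == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_equal(silhouette_score(X, lab), mean(s_hand), tolerance = 1e-9)
  # two tight, distant clusters approach 1
  Y <- rbind(c(0, 0), c(0, 0.01), c(100, 100), c(100, 100.01))
  expect_gt(silhouette_score(Y, c(1, 1, 2, 2)), 0.99)
  # random labels on structureless data sit near 0
  withr::with_seed(10, {
    Z <- matrix(rnorm(60), 30, 2)
    rl <- sample(1:2, 30, replace = TRUE)
  })
  expect_lt(abs(silhouette_score(Z, rl)), 0.1)
  expect_error(silhouette_score(X, rep(1, 7)), "two clusters")
})

test_that("cross-validation reports are structurally self-consistent", {
  ds <- tiny_dataset(n = 24, K = 2, dims = c(4, 5), class_sep = 3, seed = 77)
  cfg <- fast_config(epochs = 3L, seed = 77)
  cv <- run_cv(ds, cfg, k = 3)
  expect_identical(nrow(cv$folds), 3L)
  expect_true(all(!is.na(cv$scores$score)))
  # per-fold fusion weights live on the simplex
  sums <- dplyr::summarise(dplyr::group_by(cv$fusion_weights, fold),
                           s = sum(weight))$s
  expect_equal(sums, rep(1, 3), tolerance = 1e-9)
  # stored metrics re-derive exactly from stored scores
  for (f in 1:3) {
    test <- cv$fold_assignment[[f]]$test
    m <- compute_metrics(cv$scores$label[test], cv$scores$score[test], cfg$cutoff)
    expect_equal(as.numeric(cv$folds[f, c("acc", "auc", "sen", "spe")]),
                 as.numeric(m), tolerance = 1e-12)
  }
  # tidy/glance accessors agree with the stored tables
  expect_identical(tidy(cv), cv$folds)
  expect_identical(glance(cv)$acc_mean,
                   cv$aggregate$mean[cv$aggregate$metric == "acc"])
  expect_match(report_table(cv)$report[1], "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
})

test_that("ablation and combination runners respect their contracts", {
  ds <- tiny_dataset(n = 24, K = 2, dims = c(4, 5), class_sep = 3, seed = 81)
  cfg <- fast_config(epochs = 2L, seed = 81)
  expect_error(run_ablation(ds, cfg, variants = "bogus", k = 2), "unknown variant")
  ab <- run_ablation(ds, cfg, variants = c("full", "no_fusion"), k = 2)
  expect_identical(ab$comparison$variant, c("full", "no_fusion"))
  expect_equal(ab$comparison$p_vs_first[1], 1)        # full vs itself
  cb <- run_modality_combinations(ds, cfg, list(1, c(1, 2)), k = 2)
  expect_identical(cb$comparison$subset, c("M1", "M1+M2"))
  # the all-modality subset reproduces run_cv exactly under the same seed
  cv_full <- run_cv(ds, cfg, k = 2)
  expect_equal(cb$runs[["M1+M2"]]$folds, cv_full$folds, tolerance = 1e-12)
  expect_error(run_modality_combinations(ds, cfg, list(integer(0))), "empty")
})
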