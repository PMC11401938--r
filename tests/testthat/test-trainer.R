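make_masks <- function(n, val_every = 5) {
  idx <- seq_len(n)
  te <- idx[idx %% 4 == 0]
  tr <- setdiff(idx, te)
  val <- tr[seq(1, length(tr), by = val_every)]
  list(train = setdiff(tr, val), val = val, test = te)
}

test_that("training is bit-deterministic given one seed", {
  ds <- tiny_dataset(n = 16, K = 2, seed = 43)
  cfg <- fast_config(epochs = 4L, seed = 43)
  m <- make_masks(16)
  f1 <- fit_ampgraph(ds, cfg, m$train, m$val)
  f2 <- fit_ampgraph(ds, cfg, m$train, m$val)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$scores, f2$scores)
  expect_identical(f1$params, f2$params)
})

test_that("zero epochs returns the initialized model with an empty trace", {
  ds <- tiny_dataset(n = 12, K = 2, seed = 47)
  cfg <- fast_config(epochs = 0L)
  f <- fit_ampgraph(ds, cfg, make_masks(12)$train)
  expect_identical(nrow(f$trace), 0L)
  st0 <- init_model(zscore_normalize(ds), cfg, "full")
  expect_identical(f$params$encoder, st0$encoder)
})

test_that("the recorded joint loss recomposes from its parts via public operations", {
  ds <- tiny_dataset(n = 8, K = 2, dims = c(3, 4), seed = 53)
  cfg <- fast_config(epochs = 1L, seed = 53, normalize = FALSE)
  mask <- rep(c(TRUE, FALSE), 4)
  f <- fit_ampgraph(ds, cfg, mask, variant = "full", debug = TRUE)
  entry <- f$state$joint_entry          # parameters at joint-step entry
  # recompute L_f + beta * L_hat and L_g independently from those parameters
  obj <- encoder_objective(entry$encoder, ds, cfg, mask)
  emb <- lapply(ds$blocks, function(b) extract_features(entry$encoder, b))
  adjs <- lapply(emb, function(F)
    apply_threshold(learn_similarity(entry$W_A, F), cfg$theta))
  fused <- fuse_graphs(adjs, entry$fusion_logits)
  op <- normalize_adjacency(fused$adjacency, cfg$alpha, cfg$C)
  probs <- s2gc_forward(op, concat_features(emb), entry$classifier)
  L_g <- graph_loss(probs, ds$labels, mask)
  tr <- f$trace[1, ]
  expect_equal(tr$f_loss, obj$f_loss, tolerance = 1e-6)
  expect_equal(tr$graph_loss, L_g, tolerance = 1e-6)
  expect_equal(tr$joint_loss, L_g + cfg$eta * obj$f_loss, tolerance = 1e-6)
})

test_that("eta = 0 makes the joint step pure graph descent (encoder untouched)", {
  ds <- tiny_dataset(n = 8, K = 2, dims = c(3, 4), seed = 59)
  cfg <- fast_config(epochs = 1L, eta = 0, seed = 59)
  f <- fit_ampgraph(ds, cfg, rep(c(TRUE, FALSE), 4), variant = "full", debug = TRUE)
  # extractors identical between joint-step entry and end of epoch
  expect_identical(f$state$encoder$extractors, f$state$joint_entry$encoder$extractors)
})

test_that("masks must not overlap and non-finite losses abort loudly", {
  ds <- tiny_dataset(n = 8, K = 2, seed = 61)
  cfg <- fast_config(epochs = 1L)
  st <- init_model(ds, cfg)
  expect_error(train_epoch(st, ds, rep(TRUE, 8), rep(c(TRUE, FALSE), 4)), "overlap")
  st$encoder$extractors[[1]]$W1[1, 1] <- NaN
  expect_error(train_epoch(st, ds, rep(c(TRUE, FALSE), 4)), "non-finite")
})

test_that("the discriminator improves over the course of the adversarial game", {
  spec <- synthetic_spec(n_subjects = 60, n_modalities = 3, dims = c(6, 8, 10),
                         class_sep = 2, modality_shift = 5, seed = 67)
  ds <- generate_synthetic(spec)
  cfg <- run_config(epochs = 150L, d_c = 8L, seed = 67)
  f <- fit_ampgraph(ds, cfg, make_masks(60)$train, variant = "full")
  d <- f$trace$d_loss
  # at its published learning rate the discriminator moves slowly; compare the
  # opening phase with the closing phase of the minimax game
  expect_lt(mean(d[141:150]), mean(d[1:10]))
})

test_that("variant contracts hold: no_fusion never builds an adjacency", {
  ds <- tiny_dataset(n = 10, K = 2, seed = 71)
  cfg <- fast_config(epochs = 2L)
  f <- fit_ampgraph(ds, cfg, rep(c(TRUE, FALSE), 5), variant = "no_fusion")
  expect_true(all(is.na(f$fusion_weights)))
  expect_error(fitted_adjacency(f), "no adjacency")
  f2 <- fit_ampgraph(ds, cfg, rep(c(TRUE, FALSE), 5), variant = "full")
  A <- fitted_adjacency(f2)
  expect_identical(dim(A), c(10L, 10L))
  expect_lt(max(abs(A - t(A))), 1e-12)
  expect_equal(sum(f2$fusion_weights), 1, tolerance = 1e-12)
})

test_that("trained embeddings separate the classes better than raw features", {
  spec <- synthetic_spec(n_subjects = 100, n_modalities = 2, dims = c(10, 30),
                         class_sep = 4, modality_shift = 3, seed = 7)
  ds <- generate_synthetic(spec)
  f <- fit_ampgraph(ds, run_config(epochs = 80L, d_c = 8L, seed = 7),
                    which(seq_len(100) %% 5 != 0), variant = "extractor_only")
  raw <- do.call(cbind, lapply(zscore_normalize(ds)$blocks, `[[`, "features"))
  expect_gt(silhouette_score(fitted_embeddings(f), ds$labels),
            silhouette_score(raw, ds$labels))
})

test_that("the two-layer graph-convolution classifier variant trains", {
  ds <- tiny_dataset(n = 12, K = 2, seed = 73)
  cfg <- fast_config(epochs = 3L, classifier = "gcn2")
  f <- fit_ampgraph(ds, cfg, rep(c(TRUE, FALSE), 6))
  expect_true(all(is.finite(f$trace$joint_loss)))
  expect_true(all(f$scores >= 0 & f$scores <= 1))
})
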