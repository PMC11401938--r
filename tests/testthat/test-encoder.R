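test_that("the extractor forward pass matches a layer-by-layer hand computation", {
  ds <- tiny_dataset(n = 4, K = 1, dims = 3, seed = 13)
  cfg <- fast_config(d_c = 5L)
  enc <- init_encoder(ds, cfg)
  F <- extract_features(enc, ds$blocks[[1]])
  # independent hand computation with explicit Leaky-ReLU
  lrelu <- function(x) ifelse(x > 0, x, 0.01 * x)
  p <- enc$extractors[[1]]
  X <- ds$blocks[[1]]$features
  H1 <- lrelu(sweep(X %*% p$W1, 2, p$b1, "+"))
  H2 <- lrelu(sweep(H1 %*% p$W2, 2, p$b2, "+"))
  expect_equal(F, H2, tolerance = 1e-6)
  expect_identical(dim(F), c(4L, 5L))
})

test_that("all-zero weights give all-zero embeddings and positives pass through", {
  ds <- tiny_dataset(n = 4, K = 1, dims = 3, seed = 13)
  enc <- init_encoder(ds, fast_config(d_c = 5L))
  enc$extractors[[1]] <- rapply(enc$extractors[[1]], function(x) x * 0, how = "replace")
  expect_true(all(extract_features(enc, ds$blocks[[1]]) == 0))

  # 1-feature pass-through: Leaky-ReLU is the identity on positive inputs
  ids <- paste0("S", 1:3)
  blk <- modality_block(matrix(c(0.5, 1, 2)), ids, "M1")
  enc1 <- list(extractors = list(M1 = list(
    W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0,
    Wh = matrix(0, 1, 2), bh = c(0, 0))))
  expect_equal(unname(extract_features(enc1, blk)[, 1]), c(0.5, 1, 2))
  expect_error(extract_features(enc1, modality_block(matrix(1:6, 3, 2), ids, "M1")),
               "dimension mismatch")
})

test_that("adversarial loss hits its closed-form anchors", {
  setup <- perfect_disc_setup()
  # (near-)perfect true-modality discrimination: loss 0
  expect_lt(adversarial_loss(setup$disc, setup$emb, use_inverted = FALSE), 1e-9)
  # inverted labels against a perfect discriminator: 2 per sample per modality
  expect_equal(adversarial_loss(setup$disc, setup$emb, use_inverted = TRUE),
               4, tolerance = 1e-9)
  expect_equal(adversarial_loss(setup$disc, setup$emb, use_inverted = TRUE,
                                strategy = "flip"),
               4, tolerance = 1e-9)
  # an uninformative discriminator outputs (0.5, 0.5): per-modality term 0.5
  disc0 <- list(W1 = matrix(0, 2, 2), b1 = c(0, 0), W2 = matrix(0, 2, 2), b2 = c(0, 0))
  expect_equal(adversarial_loss(disc0, setup$emb), 1, tolerance = 1e-12)
})

test_that("inverted targets form valid distributions over the wrong modalities", {
  for (K in 2:5) {
    Tg <- ampgraph:::.modality_targets(K, inverted = TRUE, strategy = "uniform")
    expect_equal(rowSums(Tg), rep(1, K))
    expect_true(all(diag(Tg) == 0))
  }
  expect_error(ampgraph:::.modality_targets(3, TRUE, "flip"), "K = 2")
})

test_that("classification loss anchors: uniform heads give ln 2, zero weights no penalty", {
  ds <- tiny_dataset(n = 6, K = 2, seed = 17)
  enc <- init_encoder(ds, fast_config())
  # zero heads -> uniform class probabilities -> ln 2 per modality
  enc0 <- enc
  enc0$extractors <- lapply(enc0$extractors, function(p) {
    p$Wh <- p$Wh * 0; p$bh <- p$bh * 0; p
  })
  expect_equal(classification_loss(enc0, ds, rep(TRUE, 6), tau = 0),
               2 * log(2), tolerance = 1e-12)
  # all-zero weights: tau penalty is exactly 0, loss still 2 ln 2
  encz <- enc
  encz$extractors <- lapply(encz$extractors, function(p)
    rapply(p, function(x) x * 0, how = "replace"))
  expect_equal(classification_loss(encz, ds, rep(TRUE, 6), tau = 10),
               2 * log(2), tolerance = 1e-12)
  expect_error(classification_loss(enc, ds, rep(FALSE, 6)), "empty")
})

test_that("near-perfect heads drive the classification loss to zero", {
  # embedding equals a scaled class sign; a steep head saturates the softmax
  ids <- sprintf("S%02d", 1:6)
  y <- c(0L, 1L, 0L, 1L, 1L, 0L)
  x <- ifelse(y == 1L, 1, -1) * 10
  blk <- modality_block(matrix(x), ids, "M1")
  ds <- assemble_dataset(list(blk), data.frame(subject_id = ids, label = y))
  enc <- list(extractors = list(M1 = list(
    W1 = matrix(1), b1 = 0, W2 = matrix(1), b2 = 0,
    Wh = matrix(c(-40, 40), 1, 2), bh = c(0, 0))))
  # negative inputs shrink through two Leaky-ReLUs (factor 1e-4): compensate
  enc$extractors$M1$Wh <- matrix(c(-4e5, 4e5), 1, 2)
  expect_lt(classification_loss(enc, ds, rep(TRUE, 6), tau = 0), 1e-9)
})

test_that("encoder objective composes linearly in beta", {
  ds <- tiny_dataset(n = 10, K = 2, seed = 19)
  cfg <- fast_config()
  enc <- init_encoder(ds, cfg)
  mask <- rep(c(TRUE, FALSE), 5)
  emb <- ampgraph:::embed_all(enc, ds)
  L_f <- classification_loss(enc, ds, mask, tau = cfg$tau)
  L_hat <- adversarial_loss(enc$discriminator, emb, use_inverted = TRUE)
  L_d <- adversarial_loss(enc$discriminator, emb)
  obj <- encoder_objective(enc, ds, cfg, mask)
  expect_equal(obj$f_loss, L_f + cfg$beta * L_hat, tolerance = 1e-12)
  expect_equal(obj$d_loss, L_d, tolerance = 1e-12)
  cfg0 <- cfg; cfg0$beta <- 0
  expect_equal(encoder_objective(enc, ds, cfg0, mask)$f_loss, L_f, tolerance = 1e-12)
})

test_that("both adversarial objectives are nonnegative for random models", {
  for (sd in 1:5) {
    ds <- tiny_dataset(n = 8, K = 3, dims = c(3, 4, 5), seed = sd)
    cfg <- fast_config(seed = sd)
    enc <- init_encoder(ds, cfg)
    obj <- encoder_objective(enc, ds, cfg, rep(c(TRUE, FALSE), 4))
    expect_gte(obj$f_loss, 0)
    expect_gte(obj$d_loss, 0)
    P <- discriminator_probs(enc$discriminator,
                             extract_features(enc, ds$blocks[[1]]))
    expect_equal(unname(rowSums(P)), rep(1, 8), tolerance = 1e-12)
    expect_true(all(P > 0 & P < 1))
  }
})
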