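#' Initialize the adversarial multimodal encoder
#'
#' One feature extractor per modality (two fully connected layers with
#' Leaky-ReLU activations mapping d_mk -> max(d_mk, d_c) -> d_c, plus a
#' one-layer classification head to 2 logits) and a shared modality
#' discriminator (one Leaky-ReLU hidden layer of width d_c, softmax output
#' over the K modalities).
#'
#' @param dataset A `multimodal_dataset` (architecture is sized from it).
#' @param config A [run_config()]; `d_c` and `seed` are used.
#' @return List with `extractors` (per-modality parameter lists),
#'   `discriminator`, and the layer sizes.
#' @export
init_encoder <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  withr::with_seed(config$seed, .init_encoder_raw(dataset, config$d_c))
}

# unseeded initializer; callers control the RNG scope
.init_encoder_raw <- function(dataset, d_c) {
  K <- n_modalities(dataset)
  extractors <- lapply(dataset$blocks, function(b) {
    d <- ncol(b$features); h <- max(d, d_c)
    list(W1 = init_mat(d, h), b1 = numeric(h),
         W2 = init_mat(h, d_c), b2 = numeric(d_c),
         Wh = init_mat(d_c, 2L), bh = numeric(2L))
  })
  discriminator <- list(W1 = init_mat(d_c, d_c), b1 = numeric(d_c),
                        W2 = init_mat(d_c, K), b2 = numeric(K))
  list(extractors = extractors, discriminator = discriminator,
       d_c = d_c, dims = vapply(dataset$blocks, function(b) ncol(b$features), 1L))
}

.affine <- function(X, W, b) sweep(X %*% W, 2L, b, "+")

# forward pass of one extractor with cached pre-activations
.extractor_forward <- function(p, X) {
  A1 <- .affine(X, p$W1, p$b1); H1 <- leaky_relu(A1)
  A2 <- .affine(H1, p$W2, p$b2); F <- leaky_relu(A2)
  list(X = X, A1 = A1, H1 = H1, A2 = A2, F = F)
}

.disc_forward <- function(d, F) {
  B1 <- .affine(F, d$W1, d$b1); G1 <- leaky_relu(B1)
  B2 <- .affine(G1, d$W2, d$b2)
  list(B1 = B1, G1 = G1, B2 = B2, P = softmax_rows(B2))
}

#' Map one modality block into the common embedding space
#'
#' @param encoder Encoder parameters from [init_encoder()] (or a trained
#'   model's `encoder` component).
#' @param block A `modality_block` whose name matches one of the encoder's
#'   modalities (or a bare numeric matrix together with `modality`).
#' @param modality Modality name or index; inferred from `block$name` when
#'   omitted.
#' @return N x d_c embedding matrix.
#' @export
extract_features <- function(encoder, block, modality = NULL) {
  X <- if (inherits(block, "modality_block")) block$features else as.matrix(block)
  if (is.null(modality)) {
    if (!inherits(block, "modality_block"))
      stop("`modality` must be given for a bare matrix", call. = FALSE)
    modality <- block$name
  }
  p <- encoder$extractors[[modality]]
  if (is.null(p)) stop("unknown modality: ", modality, call. = FALSE)
  if (ncol(X) != nrow(p$W1))
    stop("dimension mismatch: block has ", ncol(X), " features, extractor expects ",
         nrow(p$W1), call. = FALSE)
  .extractor_forward(p, X)$F
}

# embeddings for every modality (list of N x d_c matrices)
embed_all <- function(encoder, dataset) {
  Map(function(p, b) .extractor_forward(p, b$features)$F,
      encoder$extractors, dataset$blocks)
}

#' Discriminator modality probabilities
#'
#' @param discriminator Discriminator parameter list.
#' @param embeddings N x d_c matrix of common-space embeddings.
#' @return N x K matrix of softmax modality probabilities (rows sum to 1).
#' @export
discriminator_probs <- function(discriminator, embeddings) {
  .disc_forward(discriminator, as.matrix(embeddings))$P
}

# K x K matrix: row k is the adversarial target for modality k
.modality_targets <- function(K, inverted = FALSE, strategy = "uniform") {
  Z <- diag(K)
  if (!inverted) return(Z)
  if (K == 1L) stop("inverted labels are undefined for a single modality", call. = FALSE)
  if (strategy == "flip") {
    if (K != 2L) stop("invert strategy 'flip' is only defined for K = 2", call. = FALSE)
    return(Z[c(2L, 1L), , drop = FALSE])
  }
  if (strategy == "confusion") return(matrix(1 / K, K, K))
  (1 - Z) / (K - 1)
}

#' Squared adversarial discriminator loss
#'
#' Sum over modalities of the per-sample mean squared error between the
#' discriminator's softmax output and the modality target: the true one-hot
#' label for the discriminator's own step, or the inverted label (uniform
#' over the wrong modalities; the flip at K = 2) for the extractor's
#' alignment term.
#'
#' @param discriminator Discriminator parameters.
#' @param embeddings Named list of K embedding matrices (one per modality).
#' @param use_inverted Use inverted modality targets.
#' @param strategy `"uniform"` or `"flip"` (K = 2 only).
#' @return Scalar loss >= 0.
#' @export
adversarial_loss <- function(discriminator, embeddings, use_inverted = FALSE,
                             strategy = "uniform") {
  K <- length(embeddings)
  if (ncol(discriminator$W2) != K)
    stop("discriminator has ", ncol(discriminator$W2), " outputs but ", K,
         " modalities were supplied", call. = FALSE)
  Tg <- .modality_targets(K, use_inverted, strategy)
  total <- 0
  for (k in seq_len(K)) {
    P <- .disc_forward(discriminator, embeddings[[k]])$P
    r <- sweep(P, 2L, Tg[k, ])
    total <- total + mean(rowSums(r^2))
  }
  total
}

#' Per-modality supervised classification loss of the encoder
#'
#' Sum over modalities of the mean cross-entropy of each modality head on
#' the labelled training subjects, plus `tau` times the sum of squared
#' extractor weights (L2 penalty; biases excluded). Test subjects never
#' enter this loss.
#'
#' @param encoder Encoder parameters.
#' @param dataset A `multimodal_dataset`.
#' @param train_mask Logical vector of length N (or integer indices) marking
#'   the labelled training subjects.
#' @param tau Weight-penalty coefficient.
#' @return Scalar loss >= 0.
#' @export
classification_loss <- function(encoder, dataset, train_mask, tau = 0) {
  mask <- .as_mask(train_mask, n_subjects(dataset))
  if (!any(mask)) stop("empty training mask", call. = FALSE)
  y <- dataset$labels[mask]
  total <- 0
  for (k in seq_along(dataset$blocks)) {
    p <- encoder$extractors[[k]]
    F <- .extractor_forward(p, dataset$blocks[[k]]$features)$F
    P <- softmax_rows(.affine(F[mask, , drop = FALSE], p$Wh, p$bh))
    total <- total + mean(-log(pmax(P[cbind(seq_along(y), y + 1L)], 1e-12)))
  }
  pen <- sum(vapply(encoder$extractors,
                    function(p) sum(p$W1^2) + sum(p$W2^2) + sum(p$Wh^2), numeric(1)))
  total + tau * pen
}

.as_mask <- function(mask, n) {
  if (is.logical(mask)) { stopifnot(length(mask) == n); return(mask) }
  out <- rep(FALSE, n); out[mask] <- TRUE; out
}

#' The two scalar objectives of the adversarial game
#'
#' The extractor minimizes `f_loss = L_f + beta * L_hat` (classification loss
#' plus the invert-label alignment term); the discriminator minimizes
#' `d_loss` (squared loss against true modality labels).
#'
#' @inheritParams classification_loss
#' @param config A [run_config()] supplying `beta`, `tau`, `invert_strategy`.
#' @return List with numeric scalars `f_loss` and `d_loss`.
#' @export
encoder_objective <- function(encoder, dataset, config, train_mask) {
  stopifnot(config$beta >= 0)
  emb <- embed_all(encoder, dataset)
  L_f <- classification_loss(encoder, dataset, train_mask, tau = config$tau)
  L_hat <- adversarial_loss(encoder$discriminator, emb, use_inverted = TRUE,
                            strategy = config$invert_strategy)
  L_d <- adversarial_loss(encoder$discriminator, emb, use_inverted = FALSE)
  list(f_loss = L_f + config$beta * L_hat, d_loss = L_d)
}

# gradient of sum_c (p_c - t_c)^2 through the softmax, per row; scale applied
.sq_softmax_grad <- function(P, target_row, scale) {
  r <- sweep(P, 2L, target_row)
  s <- rowSums(P * r)
  2 * scale * (P * r - P * s)
}

# ---- discriminator step gradients ------------------------------------------
# d_loss = sum_k mean_i ||softmax(d(F_k_i)) - z_k||^2, embeddings fixed
disc_grad <- function(discriminator, embeddings) {
  K <- length(embeddings)
  Tg <- .modality_targets(K)
  g <- list(W1 = discriminator$W1 * 0, b1 = discriminator$b1 * 0,
            W2 = discriminator$W2 * 0, b2 = discriminator$b2 * 0)
  loss <- 0
  for (k in seq_len(K)) {
    F <- embeddings[[k]]; N <- nrow(F)
    fw <- .disc_forward(discriminator, F)
    r <- sweep(fw$P, 2L, Tg[k, ])
    loss <- loss + mean(rowSums(r^2))
    dB2 <- .sq_softmax_grad(fw$P, Tg[k, ], 1 / N)
    g$W2 <- g$W2 + crossprod(fw$G1, dB2); g$b2 <- g$b2 + colSums(dB2)
    dB1 <- (dB2 %*% t(discriminator$W2)) * leaky_relu_grad(fw$B1)
    g$W1 <- g$W1 + crossprod(F, dB1); g$b1 <- g$b1 + colSums(dB1)
  }
  list(grads = g, d_loss = loss)
}

# ---- extractor step gradients ----------------------------------------------
# f_loss = L_f + beta * L_hat; discriminator frozen, gradients reach the
# extractors through it. Returns grads shaped like encoder$extractors.
encoder_grad <- function(encoder, dataset, config, train_mask) {
  mask <- .as_mask(train_mask, n_subjects(dataset))
  n_tr <- sum(mask)
  y <- dataset$labels
  K <- length(dataset$blocks)
  Tg <- if (config$beta > 0)
    .modality_targets(K, inverted = TRUE, strategy = config$invert_strategy)
  d <- encoder$discriminator
  grads <- vector("list", K); names(grads) <- names(encoder$extractors)
  L_f <- 0; L_hat <- 0
  for (k in seq_len(K)) {
    p <- encoder$extractors[[k]]
    fw <- .extractor_forward(p, dataset$blocks[[k]]$features)
    N <- nrow(fw$F)
    # supervised head (train rows only)
    logits <- .affine(fw$F, p$Wh, p$bh)
    Pc <- softmax_rows(logits)
    L_f <- L_f + mean(-log(pmax(Pc[mask, , drop = FALSE][cbind(seq_len(n_tr), y[mask] + 1L)], 1e-12)))
    Yoh <- cbind(1 - y, y)
    dLog <- (Pc - Yoh) / n_tr
    dLog[!mask, ] <- 0
    dWh <- crossprod(fw$F, dLog) + 2 * config$tau * p$Wh
    dbh <- colSums(dLog)
    dF <- dLog %*% t(p$Wh)
    # adversarial alignment term (all rows, frozen discriminator)
    if (config$beta > 0) {
      dfw <- .disc_forward(d, fw$F)
      r <- sweep(dfw$P, 2L, Tg[k, ])
      L_hat <- L_hat + mean(rowSums(r^2))
      dB2 <- .sq_softmax_grad(dfw$P, Tg[k, ], config$beta / N)
      dB1 <- (dB2 %*% t(d$W2)) * leaky_relu_grad(dfw$B1)
      dF <- dF + dB1 %*% t(d$W1)
    }
    dA2 <- dF * leaky_relu_grad(fw$A2)
    dW2 <- crossprod(fw$H1, dA2) + 2 * config$tau * p$W2
    db2 <- colSums(dA2)
    dA1 <- (dA2 %*% t(p$W2)) * leaky_relu_grad(fw$A1)
    dW1 <- crossprod(fw$X, dA1) + 2 * config$tau * p$W1
    db1 <- colSums(dA1)
    grads[[k]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wh = dWh, bh = dbh)
  }
  pen <- sum(vapply(encoder$extractors,
                    function(p) sum(p$W1^2) + sum(p$W2^2) + sum(p$Wh^2), numeric(1)))
  list(grads = grads, f_loss = L_f + config$tau * pen + config$beta * L_hat,
       L_f = L_f + config$tau * pen, L_hat = L_hat)
}

# averaged per-modality head probabilities (extractor-only predictions)
head_probs <- function(encoder, dataset) {
  K <- length(dataset$blocks)
  acc <- 0
  for (k in seq_len(K)) {
    p <- encoder$extractors[[k]]
    F <- .extractor_forward(p, dataset$blocks[[k]]$features)$F
    acc <- acc + softmax_rows(.affine(F, p$Wh, p$bh))
  }
  acc / K
}
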