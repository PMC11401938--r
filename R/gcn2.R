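# Two-layer graph-convolution classifier variant (config switch
# classifier = "gcn2"): H1 = relu(T X V1), H2 = relu(T H1 V2), then a fully
# connected layer to 2 logits. Shares the renormalized operator with S2GC.

gcn2_init <- function(F_dim, hidden) {
  list(V1 = init_mat(F_dim, hidden), V2 = init_mat(hidden, hidden),
       W = init_mat(hidden, 2L), b = numeric(2L))
}

gcn2_forward_cache <- function(op, features, params) {
  X <- as.matrix(features); Tt <- op$T_tilde
  M1 <- Tt %*% X; A1 <- M1 %*% params$V1; H1 <- pmax(A1, 0)
  M2 <- Tt %*% H1; A2 <- M2 %*% params$V2; H2 <- pmax(A2, 0)
  logits <- .affine(H2, params$W, params$b)
  list(probs = softmax_rows(logits), X = X, M1 = M1, A1 = A1, H1 = H1,
       M2 = M2, A2 = A2, H2 = H2)
}

gcn2_backward <- function(op, cache, params, labels, mask) {
  mask <- .as_mask(mask, nrow(cache$probs))
  n_tr <- sum(mask)
  Yoh <- cbind(1 - labels, labels)
  dLog <- (cache$probs - Yoh) / n_tr
  dLog[!mask, ] <- 0
  Tt <- op$T_tilde
  dW <- crossprod(cache$H2, dLog); db <- colSums(dLog)
  dA2 <- (dLog %*% t(params$W)) * (cache$A2 > 0)
  dV2 <- crossprod(cache$M2, dA2)
  dM2 <- dA2 %*% t(params$V2)
  dT <- tcrossprod(dM2, cache$H1)
  dH1 <- Tt %*% dM2                      # M2 = T H1, T symmetric
  dA1 <- dH1 * (cache$A1 > 0)
  dV1 <- crossprod(cache$M1, dA1)
  dM1 <- dA1 %*% t(params$V1)
  dT <- dT + tcrossprod(dM1, cache$X)
  list(dW = dW, db = db, dV1 = dV1, dV2 = dV2, dT = dT)
}
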