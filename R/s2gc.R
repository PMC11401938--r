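#' Renormalize a fused adjacency into a propagation operator
#'
#' Applies the renormalization trick
#' `T_tilde = (D+I)^{-1/2} (A+I) (D+I)^{-1/2}` with `D` the diagonal degree
#' matrix of the off-diagonal part of the fused adjacency (the unit
#' self-similarity diagonal is dropped first; self-loops re-enter through
#' the `+I`). The result is symmetric with spectral radius at most 1.
#'
#' @param fused N x N symmetric, entrywise nonnegative fused adjacency.
#' @param alpha Teleport weight in `[0,1]`.
#' @param C Hop count >= 1.
#' @return Object of class `propagation_operator`: `T_tilde`, `alpha`, `C`.
#' @export
normalize_adjacency <- function(fused, alpha = 0.05, C = 4L) {
  fused <- as.matrix(fused)
  if (max(abs(fused - t(fused))) > 1e-8)
    stop("fused adjacency must be symmetric", call. = FALSE)
  if (any(fused < 0)) stop("fused adjacency must be nonnegative", call. = FALSE)
  stopifnot(alpha >= 0, alpha <= 1, C >= 1)
  A0 <- fused; diag(A0) <- 0
  s <- 1 / sqrt(rowSums(A0) + 1)
  B <- A0; diag(B) <- diag(B) + 1
  T_tilde <- B * outer(s, s)
  structure(list(T_tilde = T_tilde, alpha = alpha, C = as.integer(C), s = s),
            class = "propagation_operator")
}

#' Simple Spectral Graph Convolution forward pass
#'
#' Averages the alpha-damped diffusion of the fused features over hops
#' 1..C and applies the linear head:
#' `softmax( (1/C) sum_c ((1-alpha) T^c X + alpha X) W + b )`.
#' Powers are never formed explicitly; `T^c X` is computed by iterated
#' multiplication.
#'
#' @param op A [normalize_adjacency()] operator.
#' @param features N x F fused feature matrix.
#' @param params List with `W` (F x 2) and `b` (length 2).
#' @return N x 2 matrix of class probabilities (rows sum to 1).
#' @export
s2gc_forward <- function(op, features, params) {
  s2gc_forward_cache(op, features, params)$probs
}

# forward with the intermediates needed for backprop
s2gc_forward_cache <- function(op, features, params) {
  X <- as.matrix(features)
  if (ncol(X) != nrow(params$W))
    stop("feature dimension ", ncol(X), " does not match classifier input ",
         nrow(params$W), call. = FALSE)
  Tt <- op$T_tilde; C <- op$C; a <- op$alpha
  Xc <- X; acc <- 0
  hops <- vector("list", C)                 # hops[[c]] = T^c X
  for (cc in seq_len(C)) { Xc <- Tt %*% Xc; hops[[cc]] <- Xc; acc <- acc + Xc }
  P <- a * X + ((1 - a) / C) * acc
  logits <- .affine(P, params$W, params$b)
  list(probs = softmax_rows(logits), P = P, hops = hops, X = X)
}

#' Transductive graph classification loss
#'
#' Mean cross-entropy of the propagated class probabilities over the masked
#' (labelled training) nodes only; nodes outside the mask never influence
#' the value.
#'
#' @param probs N x 2 probability matrix.
#' @param labels Integer 0/1 vector of length N.
#' @param mask Logical vector or integer indices of training nodes.
#' @return Scalar loss >= 0.
#' @export
graph_loss <- function(probs, labels, mask) {
  mask <- .as_mask(mask, nrow(probs))
  if (!any(mask)) stop("empty training mask", call. = FALSE)
  y <- labels[mask]
  mean(-log(pmax(probs[mask, , drop = FALSE][cbind(seq_along(y), y + 1L)], 1e-12)))
}

# ---- backward pass of the graph loss ---------------------------------------
# Returns gradients of L_g wrt classifier (W, b), the fused adjacency, and
# propagates on demand through threshold/fusion/cosine into W_A and the
# fusion logits. The embedding path is stop-gradient (the extractors are
# driven by the encoder losses in the joint step).
s2gc_backward <- function(op, cache, params, labels, mask) {
  mask <- .as_mask(mask, nrow(cache$P))
  n_tr <- sum(mask)
  y <- labels
  Yoh <- cbind(1 - y, y)
  dLog <- (cache$probs - Yoh) / n_tr
  dLog[!mask, ] <- 0
  dW <- crossprod(cache$P, dLog)
  db <- colSums(dLog)
  G <- dLog %*% t(params$W)                         # dL/dP, N x F
  Tt <- op$T_tilde; C <- op$C; a <- op$alpha
  # dL/dT = (1-a)/C * sum_{j=0}^{C-1} T^j G (S_{C-1-j})^T,
  # with S_t = sum_{m=0}^{t} T^m X (prefix sums of hop features)
  pre <- vector("list", C)                          # pre[[t+1]] = S_t
  pre[[1L]] <- cache$X
  if (C > 1L) for (t in seq_len(C - 1L)) pre[[t + 1L]] <- pre[[t]] + cache$hops[[t]]
  Gj <- G
  dT <- matrix(0, nrow(Tt), ncol(Tt))
  for (j in 0:(C - 1L)) {
    if (j > 0L) Gj <- Tt %*% Gj                     # T^j G (T symmetric)
    dT <- dT + tcrossprod(Gj, pre[[C - j]])
  }
  dT <- ((1 - a) / C) * dT
  list(dW = dW, db = db, dT = dT)
}

# gradient of L wrt the fused adjacency entries, given dL/dT_tilde.
# T_ij = s_i s_j B_ij with B = A0 + I, s_i = (deg_i + 1)^{-1/2}, deg_i the
# row sum of A0 (the off-diagonal part of the fused matrix). Every matrix
# entry is treated as an unconstrained variable; the symmetric forward maps
# keep the composite chain consistent. The diagonal receives no gradient
# (it is dropped before renormalization).
fused_adjacency_grad <- function(op, dT, fused) {
  s <- op$s
  A0 <- fused; diag(A0) <- 0
  B <- A0; diag(B) <- diag(B) + 1
  dA <- dT * outer(s, s)
  # via the scalings: dL/ds_i collects s_i's appearances in row i and col i
  M <- dT * B
  dLds <- as.numeric(M %*% s) + as.numeric(crossprod(M, s))
  q <- dLds * (-0.5) * s^3                          # ds_i/ddeg_i = -1/2 (deg+1)^{-3/2}
  dA <- dA + outer(q, rep(1, length(s)))            # deg_i = row sum of A0
  diag(dA) <- 0
  dA
}

# full joint-step graph gradients: classifier, W_A, fusion logits
graph_learner_grad <- function(op, cache, params, labels, mask,
                               bundle, W_A, fusion_logits, embeddings, theta) {
  bk <- s2gc_backward(op, cache, params, labels, mask)
  dA_fused <- fused_adjacency_grad(op, bk$dT, bundle$fused)
  w <- bundle$weights
  K <- length(bundle$adjacencies)
  # fusion logits: dL/dw_k = <dA_fused, A_k>; softmax jacobian
  dw <- vapply(bundle$adjacencies, function(Ak) sum(dA_fused * Ak), numeric(1))
  dlogits <- w * (dw - sum(w * dw))
  # W_A: through each thresholded cosine graph (surviving entries pass)
  dW_A <- matrix(0, nrow(W_A), ncol(W_A))
  for (k in seq_len(K)) {
    Gk <- dA_fused * w[k]
    Gk[bundle$adjacencies[[k]] == 0] <- 0           # threshold subgradient
    diag(Gk) <- 0                                   # diagonal fixed at 1
    F <- embeddings[[k]]
    U <- F %*% t(W_A)
    nrm <- sqrt(rowSums(U^2))
    Un <- U / nrm
    dUn <- (Gk + t(Gk)) %*% Un                      # A_k = Un Un^T
    dU <- (dUn - Un * rowSums(Un * dUn)) / nrm
    dW_A <- dW_A + crossprod(dU, F)                 # d(U = F W_A^T)/dW_A
  }
  list(dW = bk$dW, db = bk$db, dW_A = dW_A, dlogits = dlogits)
}
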