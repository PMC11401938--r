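#' Learnable cosine patient similarity
#'
#' Similarity between patients i and j is the cosine of their embeddings
#' after a learnable linear projection `W_A`:
#' `A_ij = cos(W_A f_i, W_A f_j)`. The matrix is symmetric with unit
#' diagonal and entries in `[-1, 1]`.
#'
#' @param W_A d_c x d_c projection matrix.
#' @param embeddings N x d_c embedding matrix (rownames used as subject IDs
#'   in error messages).
#' @return N x N similarity matrix.
#' @export
learn_similarity <- function(W_A, embeddings) {
  F <- as.matrix(embeddings)
  stopifnot(ncol(F) == ncol(W_A), nrow(W_A) == ncol(W_A))
  U <- F %*% t(W_A)
  nrm <- sqrt(rowSums(U^2))
  if (any(nrm < 1e-12)) {
    bad <- which(nrm < 1e-12)[1L]
    id <- if (!is.null(rownames(F))) rownames(F)[bad] else paste0("row ", bad)
    stop("degenerate embedding: subject ", id,
         " maps to (near-)zero under W_A", call. = FALSE)
  }
  Un <- U / nrm
  A <- tcrossprod(Un)
  A <- (A + t(A)) / 2
  A[A > 1] <- 1; A[A < -1] <- -1
  diag(A) <- 1
  A
}

#' Threshold a similarity matrix
#'
#' Off-diagonal entries below `theta` are set to zero (which removes all
#' negative cosines); the unit diagonal and symmetry are preserved. The
#' operation is idempotent.
#'
#' @param A N x N similarity matrix.
#' @param theta Threshold in `[0, 1)`.
#' @return Sparse-ified (still dense-stored) adjacency with entries in
#'   `{0} U [theta, 1]` off the diagonal.
#' @export
apply_threshold <- function(A, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1)
    stop("`theta` must be a scalar in [0, 1)", call. = FALSE)
  d <- diag(A)
  A[A < theta] <- 0
  diag(A) <- d
  A
}

#' Fuse per-modality graphs by learned simplex weights
#'
#' Fusion weights are the softmax of K unconstrained logits, so they are
#' strictly positive and sum to one; the global adjacency is the weighted
#' sum of the per-modality adjacencies and is directly interpretable as
#' per-modality importance.
#'
#' @param adjacencies List of K same-shaped symmetric matrices.
#' @param fusion_logits Numeric K-vector.
#' @return List with `adjacency` (the fused matrix) and `weights` (the
#'   simplex K-vector).
#' @export
fuse_graphs <- function(adjacencies, fusion_logits) {
  K <- length(adjacencies)
  stopifnot(K >= 1L, length(fusion_logits) == K)
  dims <- vapply(adjacencies, dim, integer(2))
  if (any(dims != dims[1L]))
    stop("adjacency shape mismatch across modalities", call. = FALSE)
  w <- exp(fusion_logits - max(fusion_logits))
  w <- w / sum(w)
  A <- Reduce(`+`, Map(`*`, adjacencies, as.list(w)))
  list(adjacency = A, weights = as.numeric(w))
}

#' Concatenate aligned embeddings
#'
#' Column-binds the K per-modality embedding matrices into the fused feature
#' matrix (N x K*d_c), modality blocks in order.
#'
#' @param embeddings List of K matrices with identical N and d_c.
#' @return N x (K*d_c) matrix.
#' @export
concat_features <- function(embeddings) {
  stopifnot(length(embeddings) >= 1L)
  ns <- vapply(embeddings, nrow, 1L); ds <- vapply(embeddings, ncol, 1L)
  if (length(unique(ns)) != 1L || length(unique(ds)) != 1L)
    stop("all embedding matrices must share N and d_c", call. = FALSE)
  do.call(cbind, embeddings)
}

#' Raw-feature cosine patient graph (untrained baseline)
#'
#' Cosine-similarity graph computed per modality on the (z-scored)
#' raw features, thresholded and uniformly averaged: the untrained
#' counterpart of the learned fused adjacency, used as the reference
#' in graph-recovery comparisons.
#'
#' @param dataset A `multimodal_dataset`.
#' @param theta Similarity threshold, as in [apply_threshold()].
#' @param normalize Z-score the features first (default TRUE).
#' @return N x N fused raw-similarity adjacency.
#' @export
raw_similarity_graph <- function(dataset, theta = 0.3, normalize = TRUE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (normalize) dataset <- zscore_normalize(dataset)
  adjs <- lapply(dataset$blocks, function(b) {
    X <- b$features
    nrm <- sqrt(rowSums(X^2))
    nrm[nrm < 1e-12] <- 1
    A <- tcrossprod(X / nrm)
    A[A > 1] <- 1; A[A < -1] <- -1
    diag(A) <- 1
    apply_threshold(A, theta)
  })
  fuse_graphs(adjs, numeric(length(adjs)))$adjacency
}

# full graph bundle from embeddings: per-modality thresholded adjacencies,
# fused adjacency + weights, concatenated features
build_graph_bundle <- function(W_A, fusion_logits, embeddings, theta) {
  adjs <- lapply(embeddings, function(F) apply_threshold(learn_similarity(W_A, F), theta))
  fused <- fuse_graphs(adjs, fusion_logits)
  list(adjacencies = adjs, fused = fused$adjacency, weights = fused$weights,
       features = concat_features(embeddings))
}
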