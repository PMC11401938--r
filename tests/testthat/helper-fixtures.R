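# Small builders shared across test files. Everything is generated in code;
# no fixture files.

tiny_dataset <- function(n = 12, K = 2, dims = c(4, 5), class_sep = 2,
                         modality_shift = 2, seed = 7, latent_dim = 3) {
  generate_synthetic(synthetic_spec(
    n_subjects = n, n_modalities = K, dims = dims[seq_len(K)],
    class_sep = class_sep, modality_shift = modality_shift,
    noise_sd = 1, latent_dim = latent_dim, seed = seed))
}

fast_config <- function(...) {
  defaults <- list(epochs = 5L, d_c = 6L, seed = 3L)
  args <- utils::modifyList(defaults, list(...))
  do.call(run_config, args)
}

# independent dense-power evaluation of the diffusion classifier:
# softmax((1/C) sum_c ((1-a) T^c X + a X) W + b) with explicit matrix powers
brute_s2gc <- function(Tt, X, W, b, alpha, C) {
  acc <- matrix(0, nrow(X), ncol(X))
  Tp <- diag(nrow(Tt))
  for (cc in seq_len(C)) {
    Tp <- Tp %*% Tt
    acc <- acc + (1 - alpha) * (Tp %*% X) + alpha * X
  }
  logits <- sweep((acc / C) %*% W, 2, b, "+")
  e <- exp(logits - apply(logits, 1, max))
  e / rowSums(e)
}

# hand-built discriminator that outputs (almost exactly) the true one-hot
# for two modalities whose embeddings sit on scaled basis vectors
perfect_disc_setup <- function(n_per = 3, scale = 50) {
  emb <- list(
    M1 = matrix(rep(c(scale, 0), each = n_per), n_per, 2),
    M2 = matrix(rep(c(0, scale), each = n_per), n_per, 2)
  )
  disc <- list(W1 = diag(2), b1 = c(0, 0), W2 = 10 * diag(2), b2 = c(0, 0))
  list(emb = emb, disc = disc)
}
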