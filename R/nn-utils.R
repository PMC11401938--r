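# Small dense-network primitives shared by the encoder, graph learner and
# classifier. Everything is plain base matrix algebra so runs are
# reproducible bit-for-bit on CPU.

LRELU_SLOPE <- 0.01

leaky_relu <- function(x, slope = LRELU_SLOPE) ifelse(x > 0, x, slope * x)
leaky_relu_grad <- function(x, slope = LRELU_SLOPE) ifelse(x > 0, 1, slope)

# row-wise softmax with max subtraction; stable for logits up to ~1e4
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Glorot-style initialization
init_mat <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / (n_in + n_out))), n_in, n_out)
}

# ---- Adam over a (possibly nested) list of numeric arrays ------------------

adam_new <- function(lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L, m = NULL, v = NULL)
}

.zeros_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# clip the global L2 norm of a gradient list; guards the adversarial dynamics
clip_global_norm <- function(grads, max_norm = 5) {
  flat <- unlist(grads, use.names = FALSE)
  nrm <- sqrt(sum(flat^2))
  if (is.finite(nrm) && nrm > max_norm)
    grads <- rapply(grads, function(g) g * (max_norm / nrm), how = "replace")
  grads
}

# one Adam step; params and grads share structure. Returns list(params, state).
adam_step <- function(state, params, grads) {
  if (is.null(state$m)) { state$m <- .zeros_like(params); state$v <- .zeros_like(params) }
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  step_one <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - state$lr * (m / bc1) / (sqrt(v / bc2) + state$eps)
    list(p = p, m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, m, v)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else step_one(p, g, m, v)
  }
  res <- walk(params, grads, state$m, state$v)
  state$m <- res$m; state$v <- res$v
  list(params = res$p, state = state)
}

sum_sq <- function(p) sum(vapply(p, function(x) sum(x^2), numeric(1)))
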