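#' Initialize the full model and optimizer state
#'
#' Builds the encoder (extractors + discriminator), the graph learner
#' (`W_A` initialized at the identity, fusion logits at zero so weights
#' start uniform), the classifier head, and one Adam state per parameter
#' group at the four configured learning rates.
#'
#' @param dataset A `multimodal_dataset` (already normalized if desired).
#' @param config A [run_config()].
#' @param variant One of `"full"`, `"no_discriminator"` (beta forced to 0,
#'   discriminator never updated), `"no_fusion"` (plain linear head on the
#'   concatenated embeddings; no adjacency is ever constructed),
#'   `"extractor_only"` (adversarial encoder phase only; predictions are the
#'   averaged per-modality head probabilities).
#' @return A `train_state` object: model parameters, optimizer states, empty
#'   loss trace.
#' @export
init_model <- function(dataset, config = run_config(),
                       variant = c("full", "no_discriminator", "no_fusion",
                                   "extractor_only")) {
  variant <- match.arg(variant)
  K <- n_modalities(dataset)
  F_dim <- K * config$d_c
  withr::with_seed(config$seed, {
    encoder <- .init_encoder_raw(dataset, config$d_c)
    classifier <- if (config$classifier == "gcn2" && variant %in% c("full", "no_discriminator"))
      gcn2_init(F_dim, config$d_c)
    else list(W = init_mat(F_dim, 2L), b = numeric(2L))
  })
  lr <- config$learning_rates
  structure(list(
    encoder = encoder,
    W_A = diag(config$d_c),
    fusion_logits = numeric(K),
    classifier = classifier,
    opt = list(f = adam_new(lr[1L]), d = adam_new(lr[2L]),
               a = adam_new(lr[3L]), g = adam_new(lr[4L])),
    trace = list(), epoch = 0L,
    best = list(params = NULL, val_auc = -Inf, epoch = NA_integer_),
    config = config, variant = variant
  ), class = "train_state")
}

.check_finite <- function(x, term) {
  if (!all(is.finite(x)))
    stop("non-finite value in ", term, " at training time", call. = FALSE)
  x
}

# snapshot of all learnable parameters
.params_snapshot <- function(st) {
  list(encoder = st$encoder, W_A = st$W_A,
       fusion_logits = st$fusion_logits, classifier = st$classifier)
}

# per-subject case scores under given parameters
.scores_for <- function(params, dataset, config, variant) {
  enc <- params$encoder
  if (variant == "extractor_only") return(head_probs(enc, dataset)[, 2L])
  emb <- embed_all(enc, dataset)
  fhat <- concat_features(emb)
  if (variant == "no_fusion")
    return(softmax_rows(.affine(fhat, params$classifier$W, params$classifier$b))[, 2L])
  bundle <- build_graph_bundle(params$W_A, params$fusion_logits, emb, config$theta)
  op <- normalize_adjacency(bundle$fused, config$alpha, config$C)
  probs <- if (config$classifier == "gcn2")
    gcn2_forward_cache(op, bundle$features, params$classifier)$probs
  else s2gc_forward(op, bundle$features, params$classifier)
  probs[, 2L]
}

#' Run one epoch of the alternating optimization
#'
#' Executes the published schedule: (1) one discriminator update minimizing
#' the squared true-modality loss; (2) one extractor update minimizing
#' `L_f + beta * L_hat` (invert-label alignment, discriminator frozen);
#' (3) one joint update minimizing `L_g + eta * (L_f + beta * L_hat)` in
#' which the graph learner (`W_A`, fusion logits) and the classifier descend
#' the graph loss while the extractors receive the eta-weighted encoder
#' gradients; the discriminator stays frozen. Appends
#' `(d_loss, f_loss, graph_loss, joint_loss, val_auc)` to the trace.
#'
#' @param st A `train_state` from [init_model()].
#' @param dataset The `multimodal_dataset` being fit.
#' @param train_mask,val_mask Disjoint logical masks (or index vectors) over
#'   subjects; only `train_mask` subjects enter any loss.
#' @param debug Keep the parameter snapshot taken at entry of the joint step
#'   (in `st$joint_entry`) for post-hoc loss recomposition.
#' @return The updated `train_state`.
#' @export
train_epoch <- function(st, dataset, train_mask, val_mask = NULL, debug = FALSE) {
  stopifnot(inherits(st, "train_state"))
  config <- st$config
  variant <- st$variant
  n <- n_subjects(dataset)
  train_mask <- .as_mask(train_mask, n)
  if (!is.null(val_mask)) {
    val_mask <- .as_mask(val_mask, n)
    if (any(train_mask & val_mask)) stop("train and validation masks overlap", call. = FALSE)
  }
  cfg_eff <- config
  if (variant == "no_discriminator") cfg_eff$beta <- 0
  # with a single modality the adversarial game is vacuous
  if (n_modalities(dataset) == 1L) cfg_eff$beta <- 0

  # (1) discriminator step
  emb <- embed_all(st$encoder, dataset)
  dg <- disc_grad(st$encoder$discriminator, emb)
  d_loss <- .check_finite(dg$d_loss, "discriminator loss")
  if (variant != "no_discriminator") {
    upd <- adam_step(st$opt$d, st$encoder$discriminator, clip_global_norm(dg$grads))
    st$encoder$discriminator <- upd$params; st$opt$d <- upd$state
  }

  # (2) extractor step
  eg <- encoder_grad(st$encoder, dataset, cfg_eff, train_mask)
  .check_finite(eg$f_loss, "extractor loss")
  upd <- adam_step(st$opt$f, st$encoder$extractors, clip_global_norm(eg$grads))
  st$encoder$extractors <- upd$params; st$opt$f <- upd$state

  # (3) joint step
  if (debug) st$joint_entry <- .params_snapshot(st)
  eg2 <- encoder_grad(st$encoder, dataset, cfg_eff, train_mask)
  f_loss <- .check_finite(eg2$f_loss, "extractor loss (joint step)")
  if (variant %in% c("full", "no_discriminator")) {
    emb2 <- embed_all(st$encoder, dataset)
    bundle <- build_graph_bundle(st$W_A, st$fusion_logits, emb2, config$theta)
    op <- normalize_adjacency(bundle$fused, config$alpha, config$C)
    if (config$classifier == "gcn2") {
      cache <- gcn2_forward_cache(op, bundle$features, st$classifier)
      g_loss <- graph_loss(cache$probs, dataset$labels, train_mask)
      bk <- gcn2_backward(op, cache, st$classifier, dataset$labels, train_mask)
      cls_grads <- list(V1 = bk$dV1, V2 = bk$dV2, W = bk$dW, b = bk$db)
      dA_fused <- fused_adjacency_grad(op, bk$dT, bundle$fused)
      gl <- .wa_logits_from_dA(dA_fused, bundle, st$W_A, emb2)
    } else {
      cache <- s2gc_forward_cache(op, bundle$features, st$classifier)
      g_loss <- graph_loss(cache$probs, dataset$labels, train_mask)
      gr <- graph_learner_grad(op, cache, st$classifier, dataset$labels, train_mask,
                               bundle, st$W_A, st$fusion_logits, emb2, config$theta)
      cls_grads <- list(W = gr$dW, b = gr$db)
      gl <- list(dW_A = gr$dW_A, dlogits = gr$dlogits)
    }
    .check_finite(g_loss, "graph loss")
    upd <- adam_step(st$opt$a, list(W_A = st$W_A, logits = st$fusion_logits),
                     clip_global_norm(list(W_A = gl$dW_A, logits = gl$dlogits)))
    st$W_A <- upd$params$W_A; st$fusion_logits <- upd$params$logits; st$opt$a <- upd$state
    upd <- adam_step(st$opt$g, st$classifier, clip_global_norm(cls_grads))
    st$classifier <- upd$params; st$opt$g <- upd$state
  } else if (variant == "no_fusion") {
    emb2 <- embed_all(st$encoder, dataset)
    fhat <- concat_features(emb2)
    probs <- softmax_rows(.affine(fhat, st$classifier$W, st$classifier$b))
    g_loss <- graph_loss(probs, dataset$labels, train_mask)
    .check_finite(g_loss, "graph loss")
    n_tr <- sum(train_mask)
    dLog <- (probs - cbind(1 - dataset$labels, dataset$labels)) / n_tr
    dLog[!train_mask, ] <- 0
    upd <- adam_step(st$opt$g, st$classifier,
                     clip_global_norm(list(W = crossprod(fhat, dLog), b = colSums(dLog))))
    st$classifier <- upd$params; st$opt$g <- upd$state
  } else {   # extractor_only: no graph phase; trace the head loss instead
    g_loss <- graph_loss(head_probs(st$encoder, dataset), dataset$labels, train_mask)
  }
  if (config$eta > 0 && variant != "extractor_only") {
    eta_grads <- rapply(eg2$grads, function(g) config$eta * g, how = "replace")
    upd <- adam_step(st$opt$f, st$encoder$extractors, clip_global_norm(eta_grads))
    st$encoder$extractors <- upd$params; st$opt$f <- upd$state
  }

  joint_loss <- g_loss + config$eta * f_loss
  val_auc <- NA_real_
  if (!is.null(val_mask) && sum(val_mask) >= 2L &&
      length(unique(dataset$labels[val_mask])) == 2L) {
    sc <- .scores_for(.params_snapshot(st), dataset, config, variant)
    val_auc <- .rank_auc(dataset$labels[val_mask], sc[val_mask])
    # ties go to the later epoch: among equal-AUC snapshots the longer-trained
    # one has better-calibrated probabilities at the fixed cutoff
    if (is.finite(val_auc) && val_auc >= st$best$val_auc)
      st$best <- list(params = .params_snapshot(st), val_auc = val_auc,
                      epoch = st$epoch + 1L)
  }
  st$epoch <- st$epoch + 1L
  st$trace[[st$epoch]] <- c(epoch = st$epoch, d_loss = d_loss, f_loss = f_loss,
                            graph_loss = g_loss, joint_loss = joint_loss,
                            val_auc = val_auc)
  st
}

# helper used by the gcn2 joint step: W_A / logit gradients from dL/dA_fused
.wa_logits_from_dA <- function(dA_fused, bundle, W_A, embeddings) {
  w <- bundle$weights
  dw <- vapply(bundle$adjacencies, function(Ak) sum(dA_fused * Ak), numeric(1))
  dlogits <- w * (dw - sum(w * dw))
  dW_A <- matrix(0, nrow(W_A), ncol(W_A))
  for (k in seq_along(bundle$adjacencies)) {
    Gk <- dA_fused * w[k]
    Gk[bundle$adjacencies[[k]] == 0] <- 0
    diag(Gk) <- 0
    F <- embeddings[[k]]
    U <- F %*% t(W_A); nrm <- sqrt(rowSums(U^2)); Un <- U / nrm
    dUn <- (Gk + t(Gk)) %*% Un
    dU <- (dUn - Un * rowSums(Un * dUn)) / nrm
    dW_A <- dW_A + crossprod(dU, F)
  }
  list(dW_A = dW_A, dlogits = dlogits)
}

#' Fit the model on one cohort split
#'
#' Runs [train_epoch()] for `config$epochs` epochs on the full-cohort graph
#' (transductive: every subject is a node, only `train_mask` labels enter
#' losses) and retains the parameter snapshot with the best validation AUC
#' (final parameters if no validation mask is given). Deterministic given
#' `config$seed`.
#'
#' @inheritParams train_epoch
#' @param config A [run_config()].
#' @param variant Model variant, see [init_model()].
#' @return An object of class `ampgraph_fit`: final `state`, selected
#'   parameters, per-subject case scores, fusion weights, loss trace.
#' @export
fit_ampgraph <- function(dataset, config = run_config(), train_mask,
                         val_mask = NULL, variant = "full", debug = FALSE) {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  if (config$normalize) dataset <- zscore_normalize(dataset)
  st <- init_model(dataset, config, variant)
  for (e in seq_len(config$epochs))
    st <- train_epoch(st, dataset, train_mask, val_mask,
                      debug = debug && e == config$epochs)
  params <- if (!is.null(st$best$params)) st$best$params else .params_snapshot(st)
  scores <- if (config$epochs > 0) .scores_for(params, dataset, config, st$variant)
            else rep(NA_real_, n_subjects(dataset))
  weights <- if (st$variant %in% c("full", "no_discriminator") && config$epochs > 0) {
    emb <- embed_all(params$encoder, dataset)
    build_graph_bundle(params$W_A, params$fusion_logits, emb, config$theta)$weights
  } else rep(NA_real_, n_modalities(dataset))
  trace <- if (length(st$trace)) tibble::as_tibble(do.call(rbind, st$trace))
           else tibble::tibble(epoch = numeric(), d_loss = numeric(),
                               f_loss = numeric(), graph_loss = numeric(),
                               joint_loss = numeric(), val_auc = numeric())
  structure(list(
    state = st, params = params, scores = scores,
    subject_ids = dataset$subject_ids, labels = dataset$labels,
    fusion_weights = stats::setNames(weights, names(dataset$blocks)),
    trace = trace, config = config, variant = st$variant,
    train_mask = .as_mask(train_mask, n_subjects(dataset)),
    val_mask = if (is.null(val_mask)) NULL else .as_mask(val_mask, n_subjects(dataset)),
    dataset = dataset
  ), class = "ampgraph_fit")
}

#' @export
print.ampgraph_fit <- function(x, ...) {
  cat("<ampgraph_fit> variant=", x$variant, ", ", length(x$subject_ids),
      " subjects, ", nrow(x$trace), " epochs", sep = "")
  if (!is.na(x$state$best$epoch))
    cat(", best val AUC ", sprintf("%.3f", x$state$best$val_auc),
        " @ epoch ", x$state$best$epoch, sep = "")
  cat("\n")
  invisible(x)
}

#' Per-subject predictions of a fitted model
#'
#' @param object An `ampgraph_fit`.
#' @param cutoff Decision threshold; defaults to the fit's configured value.
#' @param ... Unused.
#' @return Tibble with `subject_id`, `score` (probability of class 1), and
#'   `predicted` label at the cutoff.
#' @export
predict.ampgraph_fit <- function(object, cutoff = object$config$cutoff, ...) {
  tibble::tibble(subject_id = object$subject_ids, score = object$scores,
                 predicted = as.integer(object$scores >= cutoff))
}

#' Learned common-space embeddings of a fitted model
#'
#' @param fit An `ampgraph_fit`.
#' @return N x (K*d_c) matrix of concatenated aligned embeddings.
#' @export
fitted_embeddings <- function(fit) {
  stopifnot(inherits(fit, "ampgraph_fit"))
  concat_features(embed_all(fit$params$encoder, fit$dataset))
}

#' Learned global adjacency of a fitted model
#'
#' @param fit An `ampgraph_fit` trained with a graph phase.
#' @return N x N fused adjacency matrix.
#' @export
fitted_adjacency <- function(fit) {
  stopifnot(inherits(fit, "ampgraph_fit"))
  if (!fit$variant %in% c("full", "no_discriminator"))
    stop("variant '", fit$variant, "' constructs no adjacency", call. = FALSE)
  emb <- embed_all(fit$params$encoder, fit$dataset)
  build_graph_bundle(fit$params$W_A, fit$params$fusion_logits, emb,
                     fit$config$theta)$fused
}
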