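# Mann-Whitney rank AUC; ties counted 0.5. Exact and calibration-free.
.rank_auc <- function(y, scores) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold split
#'
#' Partitions subjects into k folds with per-fold class proportions within
#' one subject of the global proportions; deterministic given the seed.
#'
#' @param labels Integer 0/1 vector.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of k elements, each `list(train = indices, test = indices)`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  stopifnot(k >= 2L)
  n <- length(labels)
  fold <- integer(n)
  withr::with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("class ", cl, " has fewer members (", length(idx),
             ") than folds (", k, ")", call. = FALSE)
      fold[sample(idx)] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  lapply(seq_len(k), function(f)
    list(train = which(fold != f), test = which(fold == f)))
}

# stratified carve of a validation subset out of training indices
.carve_validation <- function(train_idx, labels, fraction, seed) {
  val <- integer(0)
  withr::with_seed(seed, {
    for (cl in sort(unique(labels[train_idx]))) {
      idx <- train_idx[labels[train_idx] == cl]
      n_val <- max(1L, round(fraction * length(idx)))
      val <- c(val, sample(idx, n_val))
    }
  })
  list(train = setdiff(train_idx, val), val = sort(val))
}

#' Diagnostic metrics at a fixed cutoff
#'
#' ACC, AUC, sensitivity (true-positive rate among cases) and specificity
#' (true-negative rate among controls) at the given probability cutoff; AUC
#' is the Mann-Whitney rank statistic (ties counted 0.5), so it is invariant
#' to any strictly monotone transform of the scores.
#'
#' @param y_true Integer 0/1 vector (1 = case); both classes required.
#' @param scores Numeric case scores.
#' @param cutoff Decision threshold (default 0.5).
#' @return One-row tibble with `acc`, `auc`, `sen`, `spe`.
#' @export
compute_metrics <- function(y_true, scores, cutoff = 0.5) {
  if (length(unique(y_true)) < 2L)
    stop("both classes must be present in `y_true`", call. = FALSE)
  stopifnot(length(y_true) == length(scores))
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & y_true == 1L); fn <- sum(pred == 0L & y_true == 1L)
  tn <- sum(pred == 0L & y_true == 0L); fp <- sum(pred == 1L & y_true == 0L)
  tibble::tibble(
    acc = (tp + tn) / length(y_true),
    auc = .rank_auc(y_true, scores),
    sen = tp / (tp + fn),
    spe = tn / (tn + fp)
  )
}

#' Welch two-sample t-test between metric samples
#'
#' Unequal-variance (Welch) form with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. When both samples are constant the test
#' is degenerate: p = 1 if the means agree (no evidence of a difference),
#' otherwise p = 0 with an infinite statistic.
#'
#' @param a,b Numeric samples (each length >= 2).
#' @return One-row tibble with `t` and `p`.
#' @export
two_sample_t_test <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(tibble::tibble(t = 0, p = 1))
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), p = ht$p.value)
}

#' Silhouette score of a labelled embedding
#'
#' Mean over points of `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the point's own cluster and `b` the mean distance to the
#' nearest other cluster; members of singleton clusters contribute 0.
#' Higher values mean better class separation of the representation.
#'
#' @param embeddings N x d numeric matrix.
#' @param labels Cluster/class labels (>= 2 distinct values).
#' @return Scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, labels) {
  labels <- as.integer(factor(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette needs at least two clusters", call. = FALSE)
  sil <- cluster::silhouette(labels, stats::dist(as.matrix(embeddings)))
  mean(sil[, "sil_width"])
}

#' Cross-validated transductive evaluation
#'
#' Stratified k-fold protocol: per fold a stratified validation subset
#' (`config$val_fraction`, default 10%) is carved out of the training
#' subjects for snapshot selection, the patient graph is built over the
#' full cohort, only training labels enter any loss, and metrics are
#' computed on the held-out test fold at the configured cutoff. Every fold's
#' model seed derives from the root `config$seed`.
#'
#' @param dataset A `multimodal_dataset`.
#' @param config A [run_config()].
#' @param k Number of folds (default 10).
#' @param variant Model variant, see [init_model()].
#' @return An object of class `ampgraph_cv` with per-fold results
#'   (`$folds`), per-subject test scores (`$scores`), per-fold fusion
#'   weights, and aggregate mean/sd per metric.
#' @export
run_cv <- function(dataset, config = run_config(), k = 10L, variant = "full") {
  stopifnot(inherits(dataset, "multimodal_dataset"))
  folds <- stratified_kfold(dataset$labels, k, seed = config$seed)
  n <- n_subjects(dataset)
  fold_rows <- vector("list", k)
  weight_rows <- vector("list", k)
  scores_all <- rep(NA_real_, n)
  for (f in seq_len(k)) {
    fold_seed <- (config$seed + 7919L * f) %% .Machine$integer.max
    carve <- .carve_validation(folds[[f]]$train, dataset$labels,
                               config$val_fraction, fold_seed)
    cfg <- config; cfg$seed <- as.integer(fold_seed)
    fit <- fit_ampgraph(dataset, cfg,
                        train_mask = carve$train, val_mask = carve$val,
                        variant = variant)
    test <- folds[[f]]$test
    scores_all[test] <- fit$scores[test]
    m <- compute_metrics(dataset$labels[test], fit$scores[test], config$cutoff)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), m)
    weight_rows[[f]] <- tibble::tibble(fold = f,
                                       modality = names(dataset$blocks),
                                       weight = unname(fit$fusion_weights))
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  agg <- tidyr::pivot_longer(folds_tbl, -"fold", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
  structure(list(
    folds = folds_tbl, aggregate = agg,
    fusion_weights = dplyr::bind_rows(weight_rows),
    scores = tibble::tibble(subject_id = dataset$subject_ids,
                            label = dataset$labels, score = scores_all),
    k = k, variant = variant, config = config,
    fold_assignment = folds
  ), class = "ampgraph_cv")
}

#' @export
print.ampgraph_cv <- function(x, ...) {
  cat("<ampgraph_cv> ", x$k, "-fold, variant=", x$variant, "\n", sep = "")
  print(report_table(x))
  invisible(x)
}

#' Human-readable percent report of a cross-validation run
#'
#' @param cv An `ampgraph_cv`.
#' @return Tibble with metric and a `"mean +- sd"` percent string (2
#'   decimals).
#' @export
report_table <- function(cv) {
  dplyr::mutate(cv$aggregate,
                report = sprintf("%.2f ± %.2f", 100 * .data$mean, 100 * .data$sd)) |>
    dplyr::select("metric", "report")
}

#' Serialize a cross-validation report to JSON
#'
#' @param cv An `ampgraph_cv`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(cv, path) {
  out <- list(
    k = cv$k, variant = cv$variant,
    per_fold = cv$folds, aggregate = cv$aggregate,
    fusion_weights = cv$fusion_weights,
    config = unclass(cv$config)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' ROC coordinates per fold
#'
#' @param cv An `ampgraph_cv`.
#' @return Tibble with `fold`, `fpr`, `tpr` traced over score thresholds.
#' @export
roc_coordinates <- function(cv) {
  purrr::map_dfr(seq_len(cv$k), function(f) {
    test <- cv$fold_assignment[[f]]$test
    y <- cv$scores$label[test]; s <- cv$scores$score[test]
    ord <- order(s, decreasing = TRUE)
    y <- y[ord]
    tibble::tibble(fold = f,
                   fpr = c(0, cumsum(y == 0) / sum(y == 0)),
                   tpr = c(0, cumsum(y == 1) / sum(y == 1)))
  })
}

#' Ablation study over model variants
#'
#' Runs the cross-validated protocol for each requested variant on identical
#' folds (same root seed) and reports per-variant means plus a Welch t-test
#' of per-fold AUC against the full model.
#'
#' @param dataset A `multimodal_dataset`.
#' @param config A [run_config()].
#' @param variants Subset of `c("full", "no_discriminator", "no_fusion",
#'   "extractor_only")`.
#' @param k Folds.
#' @return List with `runs` (named `ampgraph_cv` list) and `comparison`
#'   tibble.
#' @export
run_ablation <- function(dataset, config = run_config(),
                         variants = c("full", "no_discriminator", "no_fusion"),
                         k = 10L) {
  allowed <- c("full", "no_discriminator", "no_fusion", "extractor_only")
  bad <- setdiff(variants, allowed)
  if (length(bad)) stop("unknown variant name: ", paste(bad, collapse = ", "), call. = FALSE)
  runs <- stats::setNames(
    lapply(variants, function(v) run_cv(dataset, config, k = k, variant = v)),
    variants)
  ref_auc <- runs[[1L]]$folds$auc
  comparison <- purrr::map_dfr(variants, function(v) {
    ag <- runs[[v]]$aggregate
    tt <- two_sample_t_test(ref_auc, runs[[v]]$folds$auc)
    tibble::tibble(variant = v,
                   acc = ag$mean[ag$metric == "acc"],
                   auc = ag$mean[ag$metric == "auc"],
                   sen = ag$mean[ag$metric == "sen"],
                   spe = ag$mean[ag$metric == "spe"],
                   t_vs_first = tt$t, p_vs_first = tt$p)
  })
  list(runs = runs, comparison = comparison)
}

#' Cross-validated comparison of modality subsets
#'
#' Runs the protocol on each subset of modalities with shared folds (same
#' root seed) and tabulates metric means; the learned fusion weights of the
#' full-modality run are attached as the modality-importance report.
#'
#' @param dataset A `multimodal_dataset`.
#' @param config A [run_config()].
#' @param subsets List of nonempty integer or name vectors of modalities.
#' @param k Folds.
#' @return List with `runs`, `comparison` tibble, and `fusion_weights` of
#'   the full set (if among the subsets).
#' @export
run_modality_combinations <- function(dataset, config = run_config(),
                                      subsets, k = 10L) {
  if (any(lengths(subsets) == 0L)) stop("empty modality subset", call. = FALSE)
  label_of <- function(s) paste(if (is.character(s)) s else names(dataset$blocks)[s],
                                collapse = "+")
  labels <- vapply(subsets, label_of, character(1))
  runs <- stats::setNames(
    lapply(subsets, function(s) run_cv(subset_modalities(dataset, s), config, k = k)),
    labels)
  comparison <- purrr::map_dfr(labels, function(l) {
    ag <- runs[[l]]$aggregate
    tibble::tibble(subset = l,
                   acc = ag$mean[ag$metric == "acc"],
                   auc = ag$mean[ag$metric == "auc"],
                   sen = ag$mean[ag$metric == "sen"],
                   spe = ag$mean[ag$metric == "spe"])
  })
  full_label <- label_of(seq_len(n_modalities(dataset)))
  fw <- if (full_label %in% labels) runs[[full_label]]$fusion_weights else NULL
  list(runs = runs, comparison = comparison, fusion_weights = fw)
}

#' Held-out accuracy of a modality-identification probe
#'
#' Trains a fresh multinomial logistic probe to predict each embedding's
#' source modality and reports held-out accuracy. Near-chance accuracy
#' (1/K) means the adversarial encoder aligned the modalities; high accuracy
#' means they remain distinguishable.
#'
#' @param embeddings List of K embedding matrices (one per modality) or an
#'   `ampgraph_fit` (its per-modality embeddings are used).
#' @param seed Seed for the probe's train/test split.
#' @param train_fraction Fraction of rows used to train the probe.
#' @return Held-out accuracy in `[0, 1]`.
#' @export
modality_probe_accuracy <- function(embeddings, seed = 1L, train_fraction = 0.5) {
  if (inherits(embeddings, "ampgraph_fit"))
    embeddings <- embed_all(embeddings$params$encoder, embeddings$dataset)
  K <- length(embeddings)
  X <- do.call(rbind, embeddings)
  y <- factor(rep(seq_len(K), vapply(embeddings, nrow, 1L)))
  withr::with_seed(seed, {
    tr <- sample(nrow(X), round(train_fraction * nrow(X)))
  })
  df <- data.frame(y = y, X)
  probe <- nnet::multinom(y ~ ., data = df[tr, ], trace = FALSE, MaxNWts = 5000)
  pred <- stats::predict(probe, newdata = df[-tr, ])
  mean(pred == y[-tr])
}
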