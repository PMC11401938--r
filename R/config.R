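#' Run configuration
#'
#' Bundles every tunable of the pipeline. Defaults follow the published
#' training recipe where one exists (trade-off `beta = 0.03`, weight penalty
#' `tau = 0.004`, joint balance `eta = 1`, teleport `alpha = 0.05`, Adam
#' learning rates 0.004/0.001/0.001/0.001 for extractor / discriminator /
#' graph learner / classifier, 500 epochs, decision cutoff 0.5); quantities
#' the recipe leaves open (`d_c`, `theta`, `C`) get documented package
#' defaults.
#'
#' @param d_c Common embedding dimension (default 16).
#' @param theta Similarity threshold in `[0,1)`; off-diagonal cosine entries
#'   below it are zeroed (default 0.3).
#' @param alpha Teleport weight in `[0,1]` balancing self-information against
#'   neighbourhood diffusion (default 0.05).
#' @param C Propagation hop count, integer >= 1 (default 4).
#' @param beta Adversarial trade-off >= 0 (default 0.03).
#' @param tau Extractor weight-penalty coefficient >= 0 (default 0.004).
#' @param eta Joint-loss balance >= 0 (default 1).
#' @param learning_rates Positive Adam rates for (extractor f, discriminator
#'   d, graph learner W_A + fusion logits, classifier g).
#' @param epochs Number of training epochs (default 500).
#' @param seed Integer root seed; every random draw derives from it.
#' @param cutoff Decision threshold in (0,1) (default 0.5).
#' @param normalize Z-score inputs on the full cohort before training
#'   (default TRUE).
#' @param invert_strategy Inverted-modality-label strategy for the extractor's
#'   adversarial term: `"uniform"` spreads mass evenly over the K-1 wrong
#'   modalities (reduces to the label flip at K = 2).
#' @param classifier `"s2gc"` (diffusion + linear head) or `"gcn2"` (two
#'   ReLU graph-convolution layers + linear head).
#' @param val_fraction Fraction of the training split carved out (stratified)
#'   for validation-based model selection (default 0.1).
#' @return An object of class `run_config` (a named list).
#' @export
run_config <- function(d_c = 16L, theta = 0.3, alpha = 0.05, C = 4L,
                       beta = 0.03, tau = 0.004, eta = 1,
                       learning_rates = c(0.004, 0.001, 0.001, 0.001),
                       epochs = 500L, seed = 1L, cutoff = 0.5,
                       normalize = TRUE,
                       invert_strategy = c("uniform", "flip"),
                       classifier = c("s2gc", "gcn2"),
                       val_fraction = 0.1) {
  invert_strategy <- match.arg(invert_strategy)
  classifier <- match.arg(classifier)
  stopifnot(d_c >= 1, theta >= 0, theta < 1, alpha >= 0, alpha <= 1,
            C >= 1, beta >= 0, tau >= 0, eta >= 0,
            length(learning_rates) == 4L, all(learning_rates > 0),
            epochs >= 0, cutoff > 0, cutoff < 1,
            val_fraction > 0, val_fraction < 1)
  structure(list(
    d_c = as.integer(d_c), theta = theta, alpha = alpha, C = as.integer(C),
    beta = beta, tau = tau, eta = eta,
    learning_rates = as.numeric(learning_rates),
    epochs = as.integer(epochs), seed = as.integer(seed), cutoff = cutoff,
    normalize = isTRUE(normalize), invert_strategy = invert_strategy,
    classifier = classifier, val_fraction = val_fraction
  ), class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) cat("  ", nm, ": ", paste(format(x[[nm]], digits = 17), collapse = " "),
                           "\n", sep = "")
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' The YAML file mirrors the [run_config()] field names one-to-one; numeric
#' values round-trip bit-exactly. Unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return For `read_run_config`, a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path, precision = 17L)
  invisible(path)
}
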