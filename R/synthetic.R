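#' Specification of a synthetic multimodal cohort
#'
#' The generator plants the two phenomena the model must handle: a shared
#' latent class structure that every informative modality observes, and a
#' per-modality affine distribution shift that makes raw modalities trivially
#' distinguishable (the condition the adversarial encoder must defeat).
#' Defaults emulate a cohort with three low-dimensional clinical blocks and
#' one high-dimensional connectivity-like block.
#'
#' @param n_subjects Cohort size N (class balance fixed at 50/50, +-1).
#' @param n_modalities Number of modality blocks K.
#' @param dims Integer vector of K feature dimensions.
#' @param class_sep Latent class-mean separation (Euclidean distance between
#'   the two class means along a fixed unit direction).
#' @param modality_shift Norm of each modality's affine offset.
#' @param noise_sd Observation noise SD (> 0).
#' @param latent_dim Dimension of the shared latent factor.
#' @param informative_modalities Indices of modalities carrying class signal
#'   (nonempty; others observe the latent factor with the class component
#'   removed).
#' @param seed Integer seed; one root generator governs all draws.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_subjects = 400L, n_modalities = 4L,
                           dims = c(20L, 30L, 40L, 120L),
                           class_sep = 4, modality_shift = 5, noise_sd = 1,
                           latent_dim = 8L,
                           informative_modalities = seq_len(n_modalities),
                           seed = 1L) {
  if (length(dims) != n_modalities)
    stop("`dims` must have length `n_modalities`", call. = FALSE)
  if (noise_sd <= 0) stop("`noise_sd` must be positive", call. = FALSE)
  if (length(informative_modalities) == 0L)
    stop("`informative_modalities` must be nonempty", call. = FALSE)
  stopifnot(n_subjects >= 4, class_sep >= 0, modality_shift >= 0, latent_dim >= 1,
            all(informative_modalities %in% seq_len(n_modalities)))
  structure(list(
    n_subjects = as.integer(n_subjects), n_modalities = as.integer(n_modalities),
    dims = as.integer(dims), class_sep = class_sep,
    modality_shift = modality_shift, noise_sd = noise_sd,
    latent_dim = as.integer(latent_dim),
    informative_modalities = as.integer(informative_modalities),
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

.unit <- function(v) v / sqrt(sum(v^2))

#' Generate a synthetic multimodal cohort
#'
#' Per subject i a latent factor z_i ~ N(c_i * (class_sep/2) * u, I) is drawn
#' (c_i = +-1 by class, u a fixed unit direction); modality k observes
#' x_i = M_k z_i + s_k + eps with a fixed random linear map M_k (the class
#' component of z is zeroed for non-informative modalities), an offset s_k of
#' norm `modality_shift`, and eps ~ N(0, noise_sd^2). Draw order (root
#' generator): class direction u, label permutation, latent noise, then per
#' modality M_k, s_k, and the noise matrix.
#'
#' @param spec A [synthetic_spec()].
#' @return A `multimodal_dataset` with modality names `M1..MK` and subject
#'   IDs `S0001...`; the latent factors are retained in attribute
#'   `"latents"` for [planted_similarity_oracle()].
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  N <- spec$n_subjects; K <- spec$n_modalities; L <- spec$latent_dim
  withr::with_seed(spec$seed, {
    u <- .unit(stats::rnorm(L))
    labels <- sample(rep(c(0L, 1L), length.out = N))
    E <- matrix(stats::rnorm(N * L), N, L)              # latent noise
    sgn <- ifelse(labels == 1L, 1, -1)
    Z <- E + (spec$class_sep / 2) * tcrossprod(sgn, u)  # informative latents
    Z0 <- E                                             # class component removed
    ids <- sprintf("S%04d", seq_len(N))
    blocks <- vector("list", K)
    class_dirs <- vector("list", K)
    for (k in seq_len(K)) {
      d <- spec$dims[k]
      M <- matrix(stats::rnorm(d * L, sd = 1 / sqrt(L)), d, L)
      s <- spec$modality_shift * .unit(stats::rnorm(d))
      noise <- matrix(stats::rnorm(N * d, sd = spec$noise_sd), N, d)
      Zk <- if (k %in% spec$informative_modalities) Z else Z0
      X <- tcrossprod(Zk, M) + matrix(s, N, d, byrow = TRUE) + noise
      blocks[[k]] <- modality_block(X, ids, paste0("M", k))
      class_dirs[[k]] <- as.numeric(M %*% u)   # planted class-mean direction
    }
  })
  ds <- assemble_dataset(blocks, tibble::tibble(subject_id = ids, label = labels))
  # assemble_dataset sorts IDs; S0001.. are already sorted so rows align
  attr(ds, "latents") <- Z
  attr(ds, "class_directions") <- class_dirs
  attr(ds, "synthetic_seed") <- spec$seed
  ds
}

#' Planted latent-similarity oracle
#'
#' Cosine similarity of the stored latent factors of a synthetic cohort: the
#' target structure a well-learned patient graph should correlate with.
#'
#' @param spec The [synthetic_spec()] that produced `dataset`.
#' @param dataset The matching `multimodal_dataset` from
#'   [generate_synthetic()].
#' @return N x N cosine-similarity matrix of the latents.
#' @export
planted_similarity_oracle <- function(spec, dataset) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(dataset, "multimodal_dataset"))
  Z <- attr(dataset, "latents")
  if (is.null(Z)) stop("dataset carries no planted latents; was it generated synthetically?",
                       call. = FALSE)
  if (nrow(Z) != spec$n_subjects || nrow(Z) != n_subjects(dataset))
    stop("spec/dataset mismatch in number of subjects", call. = FALSE)
  Zn <- Z / sqrt(rowSums(Z^2))
  tcrossprod(Zn)
}

#' Write a synthetic cohort to disk
#'
#' Emits one delimited feature table per modality, a labels table, and a
#' YAML manifest recording the generating spec — the on-disk layout
#' [load_modality_table()] and [assemble_dataset()] consume.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_cohort <- function(spec, dir) {
  ds <- generate_synthetic(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (b in ds$blocks) write_modality_table(b, file.path(dir, paste0(b$name, ".csv")))
  readr::write_csv(tibble::tibble(subject_id = ds$subject_ids, label = ds$labels),
                   file.path(dir, "labels.csv"))
  yaml::write_yaml(unclass(spec), file.path(dir, "manifest.yaml"), precision = 17L)
  invisible(dir)
}

#' Load a cohort directory written by [write_synthetic_cohort()]
#'
#' @param dir Directory containing `M*.csv` (or any non-label `.csv`
#'   modality tables) and `labels.csv`.
#' @return A `multimodal_dataset`.
#' @export
load_cohort <- function(dir) {
  labels_path <- file.path(dir, "labels.csv")
  if (!file.exists(labels_path)) stop("labels file not found: ", labels_path, call. = FALSE)
  files <- sort(setdiff(list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE),
                        labels_path))
  if (length(files) == 0L) stop("no modality tables found in ", dir, call. = FALSE)
  blocks <- lapply(files, load_modality_table)
  assemble_dataset(blocks, labels_path)
}
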