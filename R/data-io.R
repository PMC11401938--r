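#' Construct a modality block
#'
#' A modality block is one modality's numeric feature matrix for a cohort:
#' N subjects by d features, with unique subject identifiers and feature
#' names. It is the unit the per-modality feature extractors consume.
#'
#' @param features Numeric matrix (N x d) or data frame of numeric columns.
#' @param subject_ids Character vector of N unique subject identifiers.
#' @param name Modality identifier, e.g. `"PHENO"` or `"FMRI"`.
#' @param feature_names Optional character vector of length d; defaults to
#'   the column names of `features` (or `V1..Vd`).
#' @return An object of class `modality_block` with fields `name`,
#'   `subject_ids`, `features`, `feature_names`.
#' @export
modality_block <- function(features, subject_ids, name,
                           feature_names = colnames(features)) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(ncol(features)))
  subject_ids <- as.character(subject_ids)
  if (nrow(features) != length(subject_ids))
    stop("number of rows of `features` must equal length of `subject_ids`", call. = FALSE)
  if (anyDuplicated(subject_ids))
    stop("duplicate subject ID: ",
         paste(unique(subject_ids[duplicated(subject_ids)]), collapse = ", "),
         call. = FALSE)
  if (nrow(features) < 2L) stop("a modality block needs at least 2 subjects", call. = FALSE)
  if (ncol(features) < 1L) stop("a modality block needs at least 1 feature", call. = FALSE)
  if (anyNA(features) || !all(is.finite(features)))
    stop("modality block '", name, "' contains missing or non-finite values", call. = FALSE)
  dimnames(features) <- list(subject_ids, feature_names)
  structure(
    list(name = as.character(name), subject_ids = subject_ids,
         features = features, feature_names = as.character(feature_names)),
    class = "modality_block"
  )
}

#' @export
print.modality_block <- function(x, ...) {
  cat("<modality_block> ", x$name, ": ", nrow(x$features), " subjects x ",
      ncol(x$features), " features\n", sep = "")
  invisible(x)
}

# sniff "," vs "\t" from the header line
.sniff_delim <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab >= n_com && n_tab > 0L) "\t" else ","
}

#' Load one modality's feature table
#'
#' Reads a delimited text table (comma or tab separated, auto-detected) with
#' a header row and one subject-ID column; every other column must be
#' numeric. Row order is preserved.
#'
#' @param path Path to the CSV/TSV file.
#' @param id_column Name of the subject-ID column. Default `"subject_id"`.
#' @param name Modality name; defaults to the file name without extension.
#' @return A [modality_block()].
#' @export
load_modality_table <- function(path, id_column = "subject_id",
                                name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- .sniff_delim(path)
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE, show_col_types = FALSE)
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in ", path, call. = FALSE)
  ids <- as.character(df[[id_column]])
  feat_df <- df[setdiff(names(df), id_column)]
  mat <- matrix(NA_real_, nrow(feat_df), ncol(feat_df),
                dimnames = list(NULL, names(feat_df)))
  for (j in seq_along(feat_df)) {
    v <- suppressWarnings(as.numeric(feat_df[[j]]))
    bad <- which(is.na(v) & !is.na(feat_df[[j]]))
    if (anyNA(feat_df[[j]]) || length(bad)) {
      row <- if (length(bad)) bad[1L] else which(is.na(feat_df[[j]]))[1L]
      stop("non-numeric or missing cell at row ", row, ", column '",
           names(feat_df)[j], "' in ", path, call. = FALSE)
    }
    mat[, j] <- v
  }
  modality_block(mat, ids, name = name)
}

#' Write a modality block back to delimited text
#'
#' Inverse of [load_modality_table()]: values round-trip exactly (written at
#' full precision).
#'
#' @param block A [modality_block()].
#' @param path Output path; `.tsv` extension selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_modality_table <- function(block, path) {
  stopifnot(inherits(block, "modality_block"))
  df <- tibble::as_tibble(block$features)
  df <- dplyr::bind_cols(tibble::tibble(subject_id = block$subject_ids), df)
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(df, path, delim = delim)
  invisible(path)
}

#' Assemble a multimodal dataset from blocks and a labels table
#'
#' Aligns K modality blocks and a binary labels table on the intersection of
#' their subject IDs, in deterministic sorted-ID order, so downstream results
#' do not depend on per-file row order.
#'
#' @param blocks List of [modality_block()] objects.
#' @param labels_table Path to a delimited labels table with the subject-ID
#'   column and a `label` column in \{0,1\} (1 = case), or a data frame with
#'   those columns.
#' @param id_column Subject-ID column name in the labels table.
#' @return An object of class `multimodal_dataset`: fields `blocks` (aligned
#'   list of K blocks), `labels` (integer 0/1), `subject_ids`.
#' @export
assemble_dataset <- function(blocks, labels_table, id_column = "subject_id") {
  if (length(blocks) < 1L) stop("need at least one modality block", call. = FALSE)
  stopifnot(all(vapply(blocks, inherits, logical(1), "modality_block")))
  if (is.character(labels_table)) {
    if (!file.exists(labels_table)) stop("labels file not found: ", labels_table, call. = FALSE)
    delim <- .sniff_delim(labels_table)
    lab_df <- readr::read_delim(labels_table, delim = delim, progress = FALSE,
                                show_col_types = FALSE)
  } else lab_df <- as.data.frame(labels_table)
  if (!id_column %in% names(lab_df) || !"label" %in% names(lab_df))
    stop("labels table must have columns '", id_column, "' and 'label'", call. = FALSE)
  lab_ids <- as.character(lab_df[[id_column]])
  labels <- lab_df$label
  if (anyDuplicated(lab_ids)) stop("duplicate subject ID in labels table", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0/1; offending values: ",
         paste(utils::head(unique(labels[!labels %in% c(0, 1)])), collapse = ", "),
         call. = FALSE)

  shared <- Reduce(intersect, c(lapply(blocks, `[[`, "subject_ids"), list(lab_ids)))
  if (length(shared) == 0L) stop("empty subject-ID intersection across blocks and labels", call. = FALSE)
  shared <- sort(shared)
  labels <- as.integer(labels[match(shared, lab_ids)])
  if (length(unique(labels)) < 2L)
    stop("only one class present after alignment; need both cases and controls", call. = FALSE)
  blocks <- lapply(blocks, function(b) {
    idx <- match(shared, b$subject_ids)
    modality_block(b$features[idx, , drop = FALSE], shared, b$name, b$feature_names)
  })
  names(blocks) <- vapply(blocks, `[[`, character(1), "name")
  structure(list(blocks = blocks, labels = labels, subject_ids = shared),
            class = "multimodal_dataset")
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat("<multimodal_dataset> ", length(x$subject_ids), " subjects, ",
      length(x$blocks), " modalities (",
      paste0(names(x$blocks), ":", vapply(x$blocks, function(b) ncol(b$features), 1L),
             collapse = ", "),
      "); cases: ", sum(x$labels), "\n", sep = "")
  invisible(x)
}

#' Number of subjects / modalities of a dataset
#' @param dataset A `multimodal_dataset`.
#' @return Integer count.
#' @export
n_subjects <- function(dataset) length(dataset$subject_ids)

#' @rdname n_subjects
#' @export
n_modalities <- function(dataset) length(dataset$blocks)

#' Keep a subset of modalities
#'
#' @param dataset A `multimodal_dataset`.
#' @param which Integer indices or modality names.
#' @return A `multimodal_dataset` over the selected blocks.
#' @export
subset_modalities <- function(dataset, which) {
  blocks <- dataset$blocks[which]
  if (length(blocks) == 0L || any(vapply(blocks, is.null, logical(1))))
    stop("unknown modality in subset: ", paste(which, collapse = ", "), call. = FALSE)
  structure(list(blocks = blocks, labels = dataset$labels,
                 subject_ids = dataset$subject_ids),
            class = "multimodal_dataset")
}

#' Z-score features on the full cohort
#'
#' Standardizes every feature column of every modality to mean 0 and
#' standard deviation 1 using the population (divide-by-N) SD, computed on
#' the full cohort: the classifier is transductive over one patient graph,
#' so the whole cohort is visible at normalization time. Zero-variance
#' columns map to all-zeros.
#'
#' @param dataset A `multimodal_dataset` (or a single `modality_block`).
#' @return Same type as the input, standardized.
#' @export
zscore_normalize <- function(dataset) {
  norm_block <- function(b) {
    X <- b$features
    mu <- colMeans(X)
    sd_pop <- sqrt(colMeans(sweep(X, 2L, mu)^2))
    Xc <- sweep(X, 2L, mu)
    keep <- sd_pop > 0
    Xc[, keep] <- sweep(Xc[, keep, drop = FALSE], 2L, sd_pop[keep], "/")
    Xc[, !keep] <- 0
    modality_block(Xc, b$subject_ids, b$name, b$feature_names)
  }
  if (inherits(dataset, "modality_block")) return(norm_block(dataset))
  stopifnot(inherits(dataset, "multimodal_dataset"))
  dataset$blocks <- lapply(dataset$blocks, norm_block)
  dataset
}

#' Export a patient adjacency matrix
#'
#' Writes the learned global patient-similarity adjacency either as a dense
#' delimited matrix with subject-ID header/rownames, or as a weighted edge
#' list over the upper triangle (`id_i, id_j, weight`), nonzero edges only.
#'
#' @param adjacency N x N symmetric matrix.
#' @param subject_ids Character vector of length N.
#' @param path Output path.
#' @param format `"matrix"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adjacency, subject_ids, path,
                            format = c("matrix", "edgelist")) {
  format <- match.arg(format)
  n <- length(subject_ids)
  stopifnot(nrow(adjacency) == n, ncol(adjacency) == n)
  if (format == "matrix") {
    df <- tibble::as_tibble(adjacency, .name_repair = ~subject_ids)
    df <- dplyr::bind_cols(tibble::tibble(subject_id = subject_ids), df)
    readr::write_csv(df, path)
  } else {
    ut <- which(upper.tri(adjacency) & adjacency != 0, arr.ind = TRUE)
    df <- tibble::tibble(id_i = subject_ids[ut[, 1L]],
                         id_j = subject_ids[ut[, 2L]],
                         weight = adjacency[ut])
    readr::write_csv(df, path)
  }
  invisible(path)
}
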