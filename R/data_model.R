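# Core data containers: abundance matrix + per-sample metadata, and the
# TSV readers/writers shared by every stage of the pipeline.

#' Construct a profile matrix
#'
#' A profile matrix holds nonnegative abundances for a set of samples over a
#' set of features drawn from one namespace (taxonomic strains, KEGG
#' orthologs, or eggNOG orthogroups). Samples are rows, features are columns;
#' ids live in the dimnames.
#'
#' @param values Numeric matrix, samples x features, with unique rownames
#'   (sample ids) and colnames (feature ids). All values must be `>= 0`.
#' @param namespace One of `"taxonomic"`, `"kegg"`, `"eggnog"`.
#' @return An object of class `profile_matrix`: a list with elements
#'   `values`, `sample_ids`, `feature_ids`, `namespace`.
#' @export
profile_matrix <- function(values, namespace = c("taxonomic", "kegg", "eggnog")) {
  namespace <- match.arg(namespace)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  sample_ids <- rownames(values)
  feature_ids <- colnames(values)
  if (is.null(sample_ids) || is.null(feature_ids)) {
    stop("`values` must carry sample ids as rownames and feature ids as colnames")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature id: ", feature_ids[duplicated(feature_ids)][1L])
  }
  if (anyNA(values)) stop("missing values are not allowed in a profile matrix")
  if (any(values < 0)) {
    idx <- which(values < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "negative abundance at sample '%s', feature '%s'",
      sample_ids[idx[1L]], feature_ids[idx[2L]]
    ))
  }
  structure(
    list(
      values = values, sample_ids = sample_ids,
      feature_ids = feature_ids, namespace = namespace
    ),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf(
    "<profile_matrix> %d samples x %d features [%s]\n",
    length(x$sample_ids), length(x$feature_ids), x$namespace
  ))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' @param df Data frame with columns `sample_id`, `project_id`, `condition`
#'   (one of `healthy`, `crc`, `adenoma`, `small_adenoma`, `other`) and
#'   `comorbidity` (logical).
#' @return The validated data frame (class `sample_metadata` prepended).
#' @export
sample_metadata <- function(df) {
  req <- c("sample_id", "project_id", "condition", "comorbidity")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  df$project_id <- as.character(df$project_id)
  df$condition <- as.character(df$condition)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample id in metadata: ",
         df$sample_id[duplicated(df$sample_id)][1L])
  }
  bad <- setdiff(unique(df$condition), CONDITION_LEVELS)
  if (length(bad)) {
    stop("condition(s) outside the vocabulary {",
         paste(CONDITION_LEVELS, collapse = ", "), "}: ",
         paste(bad, collapse = ", "))
  }
  if (is.character(df$comorbidity)) {
    df$comorbidity <- toupper(df$comorbidity) %in% c("TRUE", "T", "1", "YES")
  }
  df$comorbidity <- as.logical(df$comorbidity)
  if (anyNA(df$comorbidity)) stop("comorbidity must be logical (TRUE/FALSE)")
  class(df) <- c("sample_metadata", "data.frame")
  df
}

#' Bundle a profile matrix with aligned sample metadata
#'
#' Every matrix sample must have exactly one metadata record and vice versa;
#' metadata rows are reordered to the matrix sample order.
#'
#' @param matrix A [profile_matrix()].
#' @param metadata A [sample_metadata()] table (or coercible data frame).
#' @return An object of class `profile_dataset` with elements `matrix` and
#'   `metadata`.
#' @export
profile_dataset <- function(matrix, metadata) {
  stopifnot(inherits(matrix, "profile_matrix"))
  metadata <- sample_metadata(metadata)
  if (!setequal(matrix$sample_ids, metadata$sample_id)) {
    only_m <- setdiff(matrix$sample_ids, metadata$sample_id)
    only_d <- setdiff(metadata$sample_id, matrix$sample_ids)
    stop(
      "matrix and metadata sample ids disagree",
      if (length(only_m)) paste0("; matrix-only: ", only_m[1L]) else "",
      if (length(only_d)) paste0("; metadata-only: ", only_d[1L]) else ""
    )
  }
  metadata <- metadata[match(matrix$sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(matrix = matrix, metadata = metadata), class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  tab <- table(x$metadata$project_id, x$metadata$condition)
  cat(sprintf(
    "<profile_dataset> %d samples x %d features [%s], %d project(s)\n",
    n_samples(x), n_features(x), x$matrix$namespace,
    length(unique(x$metadata$project_id))
  ))
  print(tab)
  invisible(x)
}

#' @rdname profile_dataset
#' @param dataset A `profile_dataset`.
#' @export
n_samples <- function(dataset) length(dataset$matrix$sample_ids)

#' @rdname profile_dataset
#' @export
n_features <- function(dataset) length(dataset$matrix$feature_ids)

#' Subset a dataset by samples or features
#'
#' @param dataset A `profile_dataset`.
#' @param samples Sample ids, logical mask, or integer indices.
#' @param features Feature ids, logical mask, or integer indices.
#' @return A `profile_dataset`.
#' @export
subset_dataset <- function(dataset, samples = NULL, features = NULL) {
  vals <- dataset$matrix$values
  meta <- dataset$metadata
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(vals))
    vals <- vals[samples, , drop = FALSE]
    meta <- meta[samples, , drop = FALSE]
  }
  if (!is.null(features)) {
    if (is.character(features)) features <- match(features, colnames(vals))
    vals <- vals[, features, drop = FALSE]
  }
  profile_dataset(profile_matrix(vals, dataset$matrix$namespace), meta)
}

#' Keep only non-ambiguous healthy/CRC samples
#'
#' Restricts a dataset to the two conditions the classifier is trained on.
#'
#' @param dataset A `profile_dataset`.
#' @param exclude_comorbid Drop samples flagged as comorbid (default FALSE;
#'   the adenoma analysis applies its own comorbidity rule).
#' @return A `profile_dataset` containing only healthy and crc samples.
#' @export
binary_subset <- function(dataset, exclude_comorbid = FALSE) {
  keep <- dataset$metadata$condition %in% c("healthy", "crc")
  if (exclude_comorbid) keep <- keep & !dataset$metadata$comorbidity
  subset_dataset(dataset, samples = which(keep))
}

# 0/1 labels (crc = 1) for a dataset already reduced to the two classes.
crc_labels <- function(dataset) {
  cond <- dataset$metadata$condition
  extra <- setdiff(unique(cond), c("healthy", "crc"))
  if (length(extra)) {
    stop("dataset contains non-binary condition(s): ",
         paste(extra, collapse = ", "),
         "; use binary_subset() first")
  }
  as.integer(cond == "crc")
}

#' Read a profile TSV
#'
#' Expects the common metagenomic count-table layout: features as rows,
#' samples as columns, first column holding feature ids, header row holding
#' sample ids, tab-separated numeric body.
#'
#' @param path Path to the TSV file.
#' @inheritParams profile_matrix
#' @return A [profile_matrix()] (samples x features).
#' @export
read_profile_tsv <- function(path, namespace = c("taxonomic", "kegg", "eggnog")) {
  namespace <- match.arg(namespace)
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("no samples found in ", path)
  if (nrow(raw) == 0L) stop("no samples: file body is empty in ", path)
  feature_ids <- as.character(raw[[1L]])
  body <- raw[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      val <- body[[j]][which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1L]]
      stop(sprintf("non-numeric cell '%s' in sample column '%s'",
                   val, names(body)[j]))
    }
  }
  vals <- t(as.matrix(body))
  colnames(vals) <- feature_ids
  rownames(vals) <- names(body)
  profile_matrix(vals, namespace)
}

#' Write a profile matrix as TSV (features x samples)
#'
#' @param pm A [profile_matrix()].
#' @param path Output path.
#' @export
write_profile_tsv <- function(pm, path) {
  stopifnot(inherits(pm, "profile_matrix"))
  out <- data.frame(feature_id = pm$feature_ids,
                    t(pm$values), check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample metadata TSV
#'
#' Header: `sample_id`, `project_id`, `condition`, `comorbidity`.
#'
#' @param path Path to the TSV file.
#' @return A [sample_metadata()] table.
#' @export
read_metadata_tsv <- function(path) {
  sample_metadata(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_metadata_tsv
#' @param metadata A [sample_metadata()] table.
#' @export
write_metadata_tsv <- function(metadata, path) {
  write.table(as.data.frame(metadata), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Concatenate datasets sample-wise
#'
#' The feature space becomes the union of all feature ids; a feature absent
#' from a dataset is filled with zeros there (profiles are built on a shared
#' catalog, so absent means not observed). Sample ids must be globally
#' unique and all namespaces must agree.
#'
#' @param datasets A list of `profile_dataset` objects.
#' @return A single `profile_dataset`.
#' @export
concat_datasets <- function(datasets) {
  stopifnot(is.list(datasets), length(datasets) >= 1L)
  ns <- unique(vapply(datasets, function(d) d$matrix$namespace, character(1L)))
  if (length(ns) != 1L) {
    stop("mixed namespaces: ", paste(ns, collapse = ", "))
  }
  all_samples <- unlist(lapply(datasets, function(d) d$matrix$sample_ids))
  if (anyDuplicated(all_samples)) {
    stop("duplicate sample id across datasets: ",
         all_samples[duplicated(all_samples)][1L])
  }
  feats <- unique(unlist(lapply(datasets, function(d) d$matrix$feature_ids)))
  vals <- matrix(0, nrow = length(all_samples), ncol = length(feats),
                 dimnames = list(all_samples, feats))
  at <- 0L
  for (d in datasets) {
    n <- length(d$matrix$sample_ids)
    vals[at + seq_len(n), d$matrix$feature_ids] <- d$matrix$values
    at <- at + n
  }
  meta <- do.call(rbind, lapply(datasets, function(d) as.data.frame(d$metadata)))
  profile_dataset(profile_matrix(vals, ns), meta)
}

#' Split a multi-project dataset into per-project datasets
#'
#' @param dataset A `profile_dataset`.
#' @return Named list of `profile_dataset`, one per project id.
#' @export
split_by_project <- function(dataset) {
  projects <- unique(dataset$metadata$project_id)
  out <- lapply(projects, function(p) {
    subset_dataset(dataset, samples = which(dataset$metadata$project_id == p))
  })
  names(out) <- projects
  out
}
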