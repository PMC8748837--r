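# Validation designs: AUROC, repeated stratified CV, cross-dataset
# prediction, and leave-one-project-out with and without out-of-training
# feature selection.

#' Area under the ROC curve
#'
#' Probability that a random positive outranks a random negative, with ties
#' counted one half (the Mann-Whitney U statistic divided by `n1 * n0`).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical; 1 = positive).
#' @return AUROC in `[0, 1]`, or `NA_real_` when one class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(as.numeric(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: shuffles within class, deals folds round-robin.
# k is reduced (with a warning) when the smaller class has fewer members.
stratified_folds <- function(y, k, seed = NULL) {
  assign_folds <- function() {
    min_class <- min(table(y))
    if (min_class < k) {
      warning("reducing k from ", k, " to ", min_class,
              " (smallest class size)")
      k <- min_class
    }
    folds <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
  }
  if (is.null(seed)) assign_folds() else withr::with_seed(seed, assign_folds())
}

#' Repeated stratified k-fold cross-validation
#'
#' Selection and discretization are refit inside every training fold; the
#' held-out fold is scored with [auroc()].
#'
#' @param dataset A `profile_dataset` (restricted internally to healthy/crc).
#' @param config A [pipeline_config()].
#' @param k Folds (default 10).
#' @param repeats Repetitions (default 20).
#' @param seed Integer seed controlling the fold assignments.
#' @return Object of class `cv_result`: all per-fold AUROCs, their `mean`,
#'   and the 0.25 / 0.75 quantiles.
#' @export
repeated_cv <- function(dataset, config = pipeline_config(), k = 10L,
                        repeats = 20L, seed = 1L) {
  dataset <- binary_subset(dataset)
  y <- crc_labels(dataset)
  fold_plan <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) stratified_folds(y, k))
  })
  aurocs <- unlist(lapply(fold_plan, function(folds) {
    vapply(sort(unique(folds)), function(f) {
      train <- subset_dataset(dataset, samples = which(folds != f))
      test <- subset_dataset(dataset, samples = which(folds == f))
      fit <- fit_pipeline(train, config)
      auroc(predict_proba(fit, test), crc_labels(test))
    }, numeric(1L))
  }))
  structure(
    list(
      fold_aurocs = aurocs, mean = mean(aurocs, na.rm = TRUE),
      q25 = unname(quantile(aurocs, 0.25, na.rm = TRUE)),
      q75 = unname(quantile(aurocs, 0.75, na.rm = TRUE)),
      k = k, repeats = repeats, seed = seed
    ),
    class = "cv_result"
  )
}

#' Leave-one-project-out validation
#'
#' Each project in turn is held out; the pipeline (including feature
#' selection) is fitted on the union of the remaining projects and the
#' held-out project is scored. The per-run relevance vectors (over the full
#' feature space, zeros for unselected features) feed the consensus
#' signature.
#'
#' @param dataset Multi-project `profile_dataset` (>= 2 projects; restricted
#'   internally to healthy/crc samples).
#' @param config A [pipeline_config()].
#' @param external_mask For [olopo()]: feature ids fixed before fitting.
#' @return Object of class `lopo_result`: named per-project `auroc` and a
#'   features x projects `relevances` matrix.
#' @export
lopo <- function(dataset, config = pipeline_config(), external_mask = NULL) {
  dataset <- binary_subset(dataset)
  projects <- unique(dataset$metadata$project_id)
  if (length(projects) < 2L) stop("LOPO needs at least 2 projects")
  aurocs <- setNames(rep(NA_real_, length(projects)), projects)
  relevances <- matrix(
    0, nrow = n_features(dataset), ncol = length(projects),
    dimnames = list(dataset$matrix$feature_ids, projects)
  )
  for (p in projects) {
    held <- dataset$metadata$project_id == p
    fit <- fit_pipeline(subset_dataset(dataset, samples = which(!held)),
                        config, external_mask = external_mask)
    test <- subset_dataset(dataset, samples = which(held))
    aurocs[p] <- auroc(predict_proba(fit, test), crc_labels(test))
    relevances[, p] <- pipeline_relevance(fit)
  }
  structure(
    list(auroc = aurocs, relevances = relevances,
         external_mask = external_mask),
    class = "lopo_result"
  )
}

#' @rdname lopo
#' @export
olopo <- function(dataset, config = pipeline_config(), external_mask) {
  if (missing(external_mask) || is.null(external_mask) ||
      !length(external_mask)) {
    stop("o-LOPO requires a non-empty external feature mask")
  }
  lopo(dataset, config, external_mask = external_mask)
}

#' Cross-dataset prediction matrix
#'
#' Off-diagonal cell (r, c): train the pipeline on project r, score project
#' c. Diagonal: mean of a repeated stratified CV within the project. When
#' `include_lopo = TRUE` two extra rows report the LOPO and o-LOPO AUROCs
#' per target project (the o-LOPO feature mask defaults to the consensus
#' signature support learned from the LOPO runs). Cells whose test project
#' lacks one of the two classes are `NaN`.
#'
#' @param dataset Multi-project `profile_dataset`.
#' @param config A [pipeline_config()].
#' @param k,repeats,seed Diagonal CV parameters.
#' @param include_lopo Append the LOPO / oLOPO rows.
#' @param olopo_mask Feature ids for the oLOPO row; `NULL` derives the
#'   consensus-signature support from the LOPO relevances.
#' @return Object of class `cross_prediction_matrix` with an `auroc` matrix
#'   (rows: training sources + optional LOPO/oLOPO; columns: test projects).
#' @export
cross_dataset_matrix <- function(dataset, config = pipeline_config(),
                                 k = 10L, repeats = 20L, seed = 1L,
                                 include_lopo = FALSE, olopo_mask = NULL) {
  dataset <- binary_subset(dataset)
  projects <- unique(dataset$metadata$project_id)
  if (length(projects) < 2L) stop("need at least 2 projects")
  parts <- split_by_project(dataset)
  M <- matrix(NaN, nrow = length(projects), ncol = length(projects),
              dimnames = list(projects, projects))
  for (r in projects) {
    fit <- NULL
    # a single-class training project cannot fit: its whole row stays NaN
    if (length(unique(crc_labels(parts[[r]]))) < 2L) next
    for (cc in projects) {
      if (r == cc) {
        M[r, cc] <- repeated_cv(parts[[r]], config, k = k, repeats = repeats,
                                seed = seed)$mean
      } else {
        test_y <- crc_labels(parts[[cc]])
        if (length(unique(test_y)) < 2L) next  # undefined cell stays NaN
        if (is.null(fit)) fit <- fit_pipeline(parts[[r]], config)
        M[r, cc] <- auroc(predict_proba(fit, parts[[cc]]), test_y)
      }
    }
  }
  lopo_res <- NULL
  if (include_lopo) {
    lopo_res <- lopo(dataset, config)
    if (is.null(olopo_mask)) {
      sig <- consensus_signature(lopo_res$relevances)
      olopo_mask <- signature_support(sig)
    }
    olopo_res <- olopo(dataset, config, external_mask = olopo_mask)
    M <- rbind(M, LOPO = lopo_res$auroc[projects],
               oLOPO = olopo_res$auroc[projects])
  }
  structure(
    list(auroc = M, projects = projects, lopo = lopo_res),
    class = "cross_prediction_matrix"
  )
}
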