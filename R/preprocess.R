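# Deterministic front end of the classification pipeline:
# log(1+x) -> ANOVA-F + Benjamini-Hochberg selection -> quantile binning.

#' Elementwise log(1+x) transform
#'
#' Mitigates the skew toward large abundances common in multi-project
#' metagenomic profiles.
#'
#' @param x Nonnegative numeric matrix (or vector).
#' @return `log(1 + x)`, same shape.
#' @export
log_transform <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric")
  if (any(x < 0, na.rm = TRUE)) stop("log_transform requires nonnegative input")
  log1p(x)
}

#' Univariate ANOVA F-test selection with FDR control
#'
#' Computes a one-way F statistic per feature by explicit sums of squares,
#' corrects the p-values with Benjamini-Hochberg, and selects features with
#' `q <= alpha`. A constant feature is assigned p = 1 by definition.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Class labels (two or more groups, each with at least 2 samples).
#' @param alpha FDR level (default 0.05).
#' @return An object of class `selection_result`: `mask` (logical per
#'   feature), `p_values`, `q_values`, `alpha`.
#' @export
anova_fdr_select <- function(X, y, alpha = 0.05) {
  stopifnot(is.matrix(X), is.numeric(X))
  y <- as.factor(y)
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  counts <- table(y)
  if (length(counts) < 2L) stop("need at least two classes")
  if (any(counts < 2L)) {
    stop("class '", names(counts)[counts < 2L][1L], "' has fewer than 2 samples")
  }
  n <- nrow(X)
  k <- length(counts)
  grand <- colMeans(X)
  group_sums <- rowsum(X, y)
  group_means <- group_sums / as.vector(counts)
  ssb <- colSums(as.vector(counts) * (t(t(group_means) - grand))^2)
  sst <- colSums(X^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  fstat <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- pf(fstat, k - 1, n - k, lower.tail = FALSE)
  # constant features: no variance at all -> no evidence, p = 1
  scale_ref <- pmax(colMeans(abs(X)), 1)^2
  constant <- sst <= 1e-12 * n * scale_ref
  p[constant] <- 1
  # separated-but-constant-within: ssw == 0, ssb > 0 -> F = Inf -> p = 0
  p[!constant & ssw == 0] <- 0
  q <- p.adjust(p, method = "BH")
  structure(
    list(
      mask = q <= alpha, p_values = p, q_values = q, alpha = alpha,
      feature_ids = colnames(X)
    ),
    class = "selection_result"
  )
}

#' Equal-frequency discretizer
#'
#' Bin edges are the training quantiles `(1:(n_bins-1))/n_bins`; tied
#' quantiles collapse, so the realized bin count can be below `n_bins`
#' (a constant feature yields a single bin). `apply_discretizer()` clamps
#' out-of-range values into the first/last bin. Bin indices are 1-based.
#' A value exactly equal to an edge falls in the upper bin.
#'
#' @param X Numeric matrix (training rows only), samples x features.
#' @param n_bins Target bin count, `>= 2` (2 for taxonomic profiles, 20 for
#'   functional ones).
#' @return An object of class `discretizer`: per-feature strictly increasing
#'   edge vectors, `n_bins`, and realized bin counts.
#' @export
fit_discretizer <- function(X, n_bins) {
  stopifnot(is.matrix(X), is.numeric(X))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  probs <- seq_len(n_bins - 1L) / n_bins
  edges <- lapply(seq_len(ncol(X)), function(j) {
    e <- unique(unname(quantile(X[, j], probs = probs, type = 7,
                                names = FALSE)))
    # an edge at (or below) the minimum splits nothing: values equal to an
    # edge land in the upper bin, so such an edge leaves its lower bin empty
    e[e > min(X[, j])]
  })
  structure(
    list(
      edges = edges,
      n_bins = n_bins,
      realized_bins = vapply(edges, length, integer(1L)) + 1L,
      feature_ids = colnames(X)
    ),
    class = "discretizer"
  )
}

#' @rdname fit_discretizer
#' @param disc A fitted `discretizer`.
#' @return `apply_discretizer()`: integer matrix of bin indices, each column
#'   in `1..realized_bins[j]`.
#' @export
apply_discretizer <- function(disc, X) {
  stopifnot(inherits(disc, "discretizer"), is.matrix(X))
  if (ncol(X) != length(disc$edges)) {
    stop("feature count mismatch between discretizer and X")
  }
  B <- matrix(1L, nrow = nrow(X), ncol = ncol(X), dimnames = dimnames(X))
  for (j in seq_len(ncol(X))) {
    B[, j] <- findInterval(X[, j], disc$edges[[j]]) + 1L
  }
  B
}

#' Pipeline configuration
#'
#' @param alpha FDR level of the selection stage.
#' @param n_bins Discretization bins; `NULL` resolves by namespace (2 for
#'   taxonomic, 20 for kegg/eggnog).
#' @param learning_rate,n_epochs,n_bags EBM training parameters (see
#'   [fit_ebm()]).
#' @param seed Seed for the (optional) bagging resamples.
#' @param select Run the FDR selection stage (disabled automatically when an
#'   external mask is supplied).
#' @param on_empty What to do when no feature survives selection:
#'   `"error"` (default; silent fallback would corrupt stability statistics)
#'   or `"all"` to bypass selection explicitly.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, n_bins = NULL, learning_rate = 0.01,
                            n_epochs = 2000L, n_bags = 1L, seed = NULL,
                            select = TRUE, on_empty = c("error", "all")) {
  structure(
    list(
      alpha = alpha, n_bins = n_bins,
      ebm = ebm_config(learning_rate = learning_rate, n_epochs = n_epochs,
                       n_bags = n_bags, seed = seed),
      select = select, on_empty = match.arg(on_empty)
    ),
    class = "pipeline_config"
  )
}

resolve_n_bins <- function(config, namespace) {
  if (!is.null(config$n_bins)) return(as.integer(config$n_bins))
  if (namespace == "taxonomic") 2L else 20L
}

#' Fit the full classification pipeline
#'
#' Applies, in order: log(1+x) transform, ANOVA-F/FDR feature selection,
#' per-feature equal-frequency discretization, and the explainable boosting
#' machine. All statistics (selection, bin edges, model) are learned on the
#' training data only — unless `external_mask` supplies an out-of-training
#' feature set (the o-LOPO design), in which case the internal selection
#' stage is skipped and exactly the masked features are used.
#'
#' @param train A `profile_dataset` restricted to healthy/crc samples.
#' @param config A [pipeline_config()].
#' @param external_mask Optional character vector of feature ids fixed in
#'   advance (documented information leak of the o-LOPO comparison).
#' @return An object of class `crc_pipeline`.
#' @export
fit_pipeline <- function(train, config = pipeline_config(),
                         external_mask = NULL) {
  stopifnot(inherits(train, "profile_dataset"))
  y <- crc_labels(train)
  if (length(unique(y)) < 2L) stop("training data must contain both classes")
  X <- log_transform(train$matrix$values)
  selection <- NULL
  if (!is.null(external_mask)) {
    missing_f <- setdiff(external_mask, colnames(X))
    if (length(missing_f)) {
      stop("external mask feature(s) absent from data: ", missing_f[1L])
    }
    if (!length(external_mask)) stop("external mask is empty")
    features <- external_mask
  } else if (isTRUE(config$select)) {
    selection <- anova_fdr_select(X, y, alpha = config$alpha)
    features <- colnames(X)[selection$mask]
    if (!length(features)) {
      if (config$on_empty == "all") {
        features <- colnames(X)
      } else {
        stop("empty signature: no feature passed FDR selection at alpha = ",
             config$alpha)
      }
    }
  } else {
    features <- colnames(X)
  }
  Xs <- X[, features, drop = FALSE]
  n_bins <- resolve_n_bins(config, train$matrix$namespace)
  disc <- fit_discretizer(Xs, n_bins)
  B <- apply_discretizer(disc, Xs)
  model <- fit_ebm(B, y, config = config$ebm, n_bins = disc$realized_bins)
  structure(
    list(
      features = features, selection = selection, discretizer = disc,
      ebm = model, config = config, namespace = train$matrix$namespace,
      all_feature_ids = colnames(X)
    ),
    class = "crc_pipeline"
  )
}

#' Predict P(crc) for the samples of a dataset
#'
#' @param object A fitted `crc_pipeline`.
#' @param dataset A `profile_dataset` (any conditions).
#' @param type `"prob"` for P(crc) or `"logit"` for the additive score.
#' @param ... Unused.
#' @return Named numeric vector, one value per sample.
#' @export
predict.crc_pipeline <- function(object, dataset, type = c("prob", "logit"),
                                 ...) {
  type <- match.arg(type)
  stopifnot(inherits(dataset, "profile_dataset"))
  X <- log_transform(dataset$matrix$values)
  missing_f <- setdiff(object$features, colnames(X))
  if (length(missing_f)) {
    stop("dataset lacks pipeline feature(s): ", missing_f[1L])
  }
  B <- apply_discretizer(object$discretizer,
                         X[, object$features, drop = FALSE])
  logit <- predict_ebm_logit(object$ebm, B)
  names(logit) <- dataset$matrix$sample_ids
  if (type == "logit") logit else plogis(logit)
}

#' @rdname predict.crc_pipeline
#' @param pipeline A fitted `crc_pipeline`.
#' @export
predict_proba <- function(pipeline, dataset) {
  predict(pipeline, dataset, type = "prob")
}

#' Feature relevance of a fitted pipeline over the full feature space
#'
#' Features removed by selection carry relevance 0, so vectors from
#' different runs are comparable position-wise.
#'
#' @param pipeline A fitted `crc_pipeline`.
#' @param feature_ids Feature universe to report over (defaults to the
#'   features of the training data).
#' @return Named nonnegative numeric vector over all input features.
#' @export
pipeline_relevance <- function(pipeline, feature_ids = pipeline$all_feature_ids) {
  out <- setNames(numeric(length(feature_ids)), feature_ids)
  out[pipeline$features] <- pipeline$ebm$relevance
  out
}
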