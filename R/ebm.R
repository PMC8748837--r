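# Minimal explainable boosting machine: a generalized additive model
# g(E(y)) = b0 + sum_j f_j(x_j) on the logit link, trained by cyclic
# gradient boosting of one shape graph per (discretized) feature. The
# round-robin cycling with a small learning rate spreads attribution fairly
# across collinear features; the per-feature graphs give exact local
# attributions by construction.

#' EBM training configuration
#'
#' @param learning_rate Shrinkage applied to every per-bin boosting step
#'   (small; default 0.01).
#' @param n_epochs Full round-robin passes over the features (default 2000;
#'   the cyclic scheme relies on many passes at a small rate).
#' @param n_bags Optional bagging rounds; `1` (default) trains a single
#'   model on the full data, `> 1` averages models trained on bootstrap
#'   resamples.
#' @param seed Seed for the bagging resamples (unused when `n_bags = 1`).
#' @return An object of class `ebm_config`.
#' @export
ebm_config <- function(learning_rate = 0.01, n_epochs = 2000L, n_bags = 1L,
                       seed = NULL) {
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 1L) stop("n_epochs must be >= 1")
  structure(
    list(learning_rate = learning_rate, n_epochs = n_epochs,
         n_bags = as.integer(n_bags), seed = seed),
    class = "ebm_config"
  )
}

#' Fit an explainable boosting machine on binned features
#'
#' The intercept starts at the log-odds of the base rate with all graphs at
#' zero. Each epoch cycles over the features; for each one a per-bin mean of
#' the current log-loss gradient residuals `(y - p)` is fitted, shrunk by the
#' learning rate, added to that feature's graph, and folded into the running
#' scores. After training every graph is re-centered to zero
#' training-distribution-weighted mean (the shift moves into the intercept),
#' which makes per-feature relevances comparable.
#'
#' @param X_binned Integer matrix of 1-based bin indices, samples x features.
#' @param y Binary labels (0/1 or logical); both classes must be present.
#' @param config An [ebm_config()].
#' @param n_bins Realized bin count per feature; defaults to the per-column
#'   maximum of `X_binned`.
#' @return An object of class `ebm_model`: `intercept` (log-odds), `graphs`
#'   (per-feature per-bin contributions, training-weighted mean zero),
#'   `bin_weights`, `relevance` (mean absolute training attribution, `>= 0`),
#'   `n_bins`, `feature_ids`, `config`.
#' @export
fit_ebm <- function(X_binned, y, config = ebm_config(), n_bins = NULL) {
  stopifnot(is.matrix(X_binned))
  if (ncol(X_binned) == 0L || nrow(X_binned) == 0L) stop("empty feature matrix")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("y contains a single class")
  if (nrow(X_binned) != length(y)) stop("nrow(X_binned) must equal length(y)")
  storage.mode(X_binned) <- "integer"
  if (is.null(n_bins)) n_bins <- apply(X_binned, 2L, max)
  n_bins <- as.integer(n_bins)
  if (any(X_binned < 1L) || any(X_binned > rep(n_bins, each = nrow(X_binned)))) {
    stop("bin indices out of the declared 1..n_bins range")
  }
  intercept <- qlogis(mean(y))

  run_boost <- function(rows) {
    ebm_boost_cpp(X_binned[rows, , drop = FALSE], y[rows], n_bins,
                  config$learning_rate, config$n_epochs, intercept)$graphs
  }
  if (config$n_bags <= 1L) {
    graphs <- run_boost(seq_len(nrow(X_binned)))
  } else {
    bag <- function() {
      rows <- sample.int(nrow(X_binned), replace = TRUE)
      # resample until both classes appear
      while (length(unique(y[rows])) < 2L) {
        rows <- sample.int(nrow(X_binned), replace = TRUE)
      }
      run_boost(rows)
    }
    bags <- if (is.null(config$seed)) {
      replicate(config$n_bags, bag(), simplify = FALSE)
    } else {
      withr::with_seed(config$seed,
                       replicate(config$n_bags, bag(), simplify = FALSE))
    }
    graphs <- lapply(seq_len(ncol(X_binned)), function(j) {
      Reduce(`+`, lapply(bags, `[[`, j)) / config$n_bags
    })
  }

  # center each graph to zero training-weighted mean; shifts fold into b0
  n <- nrow(X_binned)
  bin_weights <- vector("list", ncol(X_binned))
  for (j in seq_len(ncol(X_binned))) {
    w <- tabulate(X_binned[, j], nbins = n_bins[j]) / n
    shift <- sum(w * graphs[[j]])
    graphs[[j]] <- graphs[[j]] - shift
    intercept <- intercept + shift
    bin_weights[[j]] <- w
  }

  model <- structure(
    list(
      intercept = intercept, graphs = graphs, bin_weights = bin_weights,
      n_bins = n_bins, feature_ids = colnames(X_binned), config = config
    ),
    class = "ebm_model"
  )
  model$relevance <- global_relevance(model, X_binned)
  model
}

clamp_bins <- function(model, X_binned) {
  stopifnot(is.matrix(X_binned))
  if (ncol(X_binned) != length(model$graphs)) {
    stop("feature count mismatch between model and data")
  }
  storage.mode(X_binned) <- "integer"
  for (j in seq_len(ncol(X_binned))) {
    X_binned[, j] <- pmin(pmax(X_binned[, j], 1L), model$n_bins[j])
  }
  X_binned
}

#' EBM predictions and attributions
#'
#' `predict_ebm_logit()` returns `b0 + sum_j graph_j(bin_j)` per sample;
#' `predict_ebm_proba()` is its logistic transform. Bin indices outside the
#' trained range are clamped to the nearest realized bin.
#'
#' @param model A fitted `ebm_model`.
#' @param X_binned Integer matrix of bin indices, samples x features.
#' @return Numeric vector, one value per sample.
#' @export
predict_ebm_logit <- function(model, X_binned) {
  X_binned <- clamp_bins(model, X_binned)
  out <- rep(model$intercept, nrow(X_binned))
  for (j in seq_len(ncol(X_binned))) {
    out <- out + model$graphs[[j]][X_binned[, j]]
  }
  out
}

#' @rdname predict_ebm_logit
#' @export
predict_ebm_proba <- function(model, X_binned) {
  plogis(predict_ebm_logit(model, X_binned))
}

#' Per-sample, per-feature additive contributions
#'
#' `contribution(s, j) = graph_j(bin of s in feature j)`; row sums plus the
#' intercept reproduce the logit exactly.
#'
#' @inheritParams predict_ebm_logit
#' @return Numeric matrix, samples x features.
#' @export
local_explanations <- function(model, X_binned) {
  X_binned <- clamp_bins(model, X_binned)
  out <- matrix(0, nrow = nrow(X_binned), ncol = ncol(X_binned),
                dimnames = list(rownames(X_binned), model$feature_ids))
  for (j in seq_len(ncol(X_binned))) {
    out[, j] <- model$graphs[[j]][X_binned[, j]]
  }
  out
}

#' Global feature relevance
#'
#' Aggregates the absolute local attributions over a reference set
#' (canonically the training data): `relevance_j = mean_s |contribution(s, j)|`.
#'
#' @inheritParams predict_ebm_logit
#' @return Named nonnegative numeric vector, one score per feature.
#' @export
global_relevance <- function(model, X_binned) {
  contrib <- local_explanations(model, X_binned)
  setNames(colMeans(abs(contrib)), model$feature_ids)
}

#' Serialize / restore an EBM model as JSON
#'
#' @param model A fitted `ebm_model`.
#' @param path File path.
#' @export
write_ebm_json <- function(model, path) {
  obj <- list(
    schema_version = REPORT_SCHEMA_VERSION,
    intercept = model$intercept,
    feature_ids = model$feature_ids,
    n_bins = model$n_bins,
    graphs = model$graphs,
    bin_weights = model$bin_weights,
    relevance = unname(model$relevance),
    config = list(learning_rate = model$config$learning_rate,
                  n_epochs = model$config$n_epochs,
                  n_bags = model$config$n_bags)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ebm_json
#' @export
read_ebm_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyMatrix = FALSE)
  model <- structure(
    list(
      intercept = obj$intercept,
      graphs = lapply(obj$graphs, as.numeric),
      bin_weights = lapply(obj$bin_weights, as.numeric),
      n_bins = as.integer(obj$n_bins),
      feature_ids = obj$feature_ids,
      config = do.call(ebm_config, obj$config)
    ),
    class = "ebm_model"
  )
  model$relevance <- setNames(as.numeric(obj$relevance), obj$feature_ids)
  model
}
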