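# Stability of the pipeline's explanations: agreement of the selected
# feature subsets across data splits (Nogueira estimator with its
# asymptotic confidence interval) and agreement of the relevance rankings
# (hyperbolic-weighted Kendall tau).

#' Random stability sub-sampling split plan
#'
#' Each split draws a random (class-stratified) half of the samples for
#' training; the remainder is the test half.
#'
#' @param y Class labels, one per sample (stratification; length gives the
#'   sample count, which must be >= 4).
#' @param n_splits Number of splits (default 100).
#' @param fraction Training fraction (default 0.5).
#' @param seed Integer seed.
#' @return Object of class `split_plan`: a list of `(train, test)` index
#'   pairs, with schema tag `"rsss"`.
#' @export
rsss_splits <- function(y, n_splits = 100L, fraction = 0.5, seed = 1L) {
  n <- length(y)
  if (n < 4L) stop("need at least 4 samples")
  splits <- withr::with_seed(seed, {
    lapply(seq_len(n_splits), function(s) {
      train <- integer(0)
      for (cls in unique(y)) {
        idx <- which(y == cls)
        train <- c(train, sample(idx, round(length(idx) * fraction)))
      }
      train <- sort(train)
      list(train = train, test = setdiff(seq_len(n), train))
    })
  })
  structure(list(splits = splits, schema = "rsss", seed = seed),
            class = "split_plan")
}

# 20x10-fold CV training sets reused as stability splits (the "CV-test"
# schema): each fold's training set is one row of the selection matrix.
cv_splits <- function(y, k = 10L, repeats = 20L, seed = 1L) {
  n <- length(y)
  splits <- withr::with_seed(seed, {
    out <- list()
    for (r in seq_len(repeats)) {
      folds <- stratified_folds(y, k)
      for (f in sort(unique(folds))) {
        out[[length(out) + 1L]] <- list(train = which(folds != f),
                                        test = which(folds == f))
      }
    }
    out
  })
  structure(list(splits = splits, schema = "cv", seed = seed),
            class = "split_plan")
}

#' Nogueira stability of a selection matrix
#'
#' Chance-corrected agreement of feature subsets selected across `M` splits:
#' `S = 1 - mean_f(s_f^2) / ((kbar/d) * (1 - kbar/d))` with
#' `s_f^2 = M/(M-1) * p_f (1 - p_f)` the unbiased selection-frequency
#' variance of feature `f` and `kbar` the mean subset size. 1 means perfect
#' agreement, 0 is the level of random guessing. The confidence interval
#' comes from the estimator's asymptotic normality: with influence terms
#' `phi_i = (1/v) * (mean_f z_if p_f - k_i kbar / d^2 +
#' (S/2) * (2 k_i kbar / d^2 - k_i/d - kbar/d + 1))`,
#' `Var(S) = 4/M^2 * sum_i (phi_i - mean(phi))^2` and the interval is
#' `S +/- z_{1-alpha/2} sqrt(Var)`.
#'
#' @param Z Binary matrix, splits x features (`M >= 2` rows).
#' @param alpha Confidence level complement (default 0.05).
#' @return Object of class `stability_result`: `score`, `ci_low`, `ci_high`,
#'   the reporting `thresholds` c(0.4, 0.7), `n_splits`, `n_features`.
#' @export
nogueira_stability <- function(Z, alpha = 0.05) {
  Z <- as.matrix(Z)
  if (!all(Z %in% c(0, 1))) stop("Z must be binary")
  M <- nrow(Z)
  d <- ncol(Z)
  if (M < 2L) stop("need at least 2 splits")
  p_f <- colMeans(Z)
  k_i <- rowSums(Z)
  kbar <- mean(k_i)
  if (kbar == 0 || kbar == d) {
    stop("undefined stability: every split selects ",
         if (kbar == 0) "no" else "all", " features")
  }
  v <- (kbar / d) * (1 - kbar / d)
  s2 <- (M / (M - 1)) * p_f * (1 - p_f)
  score <- 1 - mean(s2) / v
  phi <- (1 / v) * (
    (Z %*% p_f) / d - k_i * kbar / d^2 +
      (score / 2) * (2 * k_i * kbar / d^2 - k_i / d - kbar / d + 1)
  )
  variance <- (4 / M^2) * sum((phi - mean(phi))^2)
  z <- qnorm(1 - alpha / 2)
  structure(
    list(
      score = score,
      ci_low = score - z * sqrt(variance),
      ci_high = score + z * sqrt(variance),
      thresholds = c(bad = 0.4, near_perfect = 0.7),
      n_splits = M, n_features = d, alpha = alpha
    ),
    class = "stability_result"
  )
}

# 0-based midranks in decreasing order (rank 0 = most relevant; ties share
# their average position).
midrank_desc <- function(x) rank(-x, ties.method = "average") - 1

hwt_one <- function(a, b, ref) {
  w <- 1 / (1 + midrank_desc(ref))
  W <- outer(w, w, `+`)
  sa <- sign(outer(a, a, `-`))
  sb <- sign(outer(b, b, `-`))
  ut <- upper.tri(W)
  num <- sum(sa[ut] * sb[ut] * W[ut])
  da <- sum(sa[ut]^2 * W[ut])
  db <- sum(sb[ut]^2 * W[ut])
  if (da == 0 || db == 0) return(NA_real_)  # a fully tied vector has no order
  num / sqrt(da * db)
}

#' Hyperbolic-weighted Kendall tau
#'
#' A Kendall-type rank correlation in which each pair of items is weighted
#' additively by `w(r) = 1/(1 + r)` of their 0-based ranks, so discrepancies
#' near the top of the ranking cost more than those in the tail. The
#' statistic is symmetrized by averaging over which of the two vectors
#' supplies the rank weights, and normalized so that self-comparison is 1
#' and exact reversal is -1. Tied items receive the weight of their average
#' (mid) rank.
#'
#' @param a,b Numeric vectors over the same items (higher value = higher
#'   rank / more relevant).
#' @return Correlation in `[-1, 1]`.
#' @export
hwt <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch between rankings")
  if (anyNA(a) || anyNA(b)) stop("rankings must not contain missing items")
  a <- as.numeric(a)
  b <- as.numeric(b)
  (hwt_one(a, b, a) + hwt_one(a, b, b)) / 2
}

#' Rank stability across splits
#'
#' All `M(M-1)/2` pairwise [hwt()] comparisons between the per-split feature
#' relevance vectors (unselected features carry relevance 0 and share the
#' tail of the ranking).
#'
#' @param relevances Numeric matrix, features x splits (>= 2 columns), or a
#'   list of equal-length relevance vectors.
#' @return Object of class `rank_stability_result`: `mean`, `q25`, `q75`,
#'   and all pairwise `values`.
#' @export
rank_stability <- function(relevances) {
  if (is.list(relevances)) relevances <- do.call(cbind, relevances)
  stopifnot(is.matrix(relevances))
  M <- ncol(relevances)
  if (M < 2L) stop("need at least 2 splits")
  # cache per-split sign matrices and weights; pairs then reduce to sums
  ut <- upper.tri(diag(nrow(relevances)))
  signs <- lapply(seq_len(M), function(i) {
    x <- relevances[, i]
    sign(outer(x, x, `-`))[ut]
  })
  weights <- lapply(seq_len(M), function(i) {
    w <- 1 / (1 + midrank_desc(relevances[, i]))
    outer(w, w, `+`)[ut]
  })
  pair_tau <- function(i, j) {
    t_i <- {
      W <- weights[[i]]
      num <- sum(signs[[i]] * signs[[j]] * W)
      den <- sqrt(sum(signs[[i]]^2 * W) * sum(signs[[j]]^2 * W))
      if (den == 0) NA_real_ else num / den
    }
    t_j <- {
      W <- weights[[j]]
      num <- sum(signs[[i]] * signs[[j]] * W)
      den <- sqrt(sum(signs[[i]]^2 * W) * sum(signs[[j]]^2 * W))
      if (den == 0) NA_real_ else num / den
    }
    (t_i + t_j) / 2
  }
  vals <- unlist(lapply(seq_len(M - 1L), function(i) {
    vapply((i + 1L):M, function(j) pair_tau(i, j), numeric(1L))
  }))
  structure(
    list(
      mean = mean(vals, na.rm = TRUE),
      q25 = unname(quantile(vals, 0.25, na.rm = TRUE)),
      q75 = unname(quantile(vals, 0.75, na.rm = TRUE)),
      values = vals, n_splits = M
    ),
    class = "rank_stability_result"
  )
}

#' Selection- and rank-stability of the pipeline under a splitting schema
#'
#' Fits the pipeline front end on the training part of every split (RSSS
#' half-sampling or the 20x10-fold CV training sets), records which features
#' pass the FDR selection (the selection matrix) and the fitted model's
#' relevance vector, and summarizes both with [nogueira_stability()] and
#' [rank_stability()].
#'
#' @param dataset A `profile_dataset` (restricted internally to healthy/crc).
#' @param config A [pipeline_config()].
#' @param schema `"rsss"` (default; 100 stratified half splits) or `"cv"`.
#' @param n_splits RSSS splits (ignored for `"cv"`).
#' @param k,repeats CV schema parameters.
#' @param seed Integer seed.
#' @return List with elements `selection` (a `stability_result`), `rank`
#'   (a `rank_stability_result`), the binary `selection_matrix`, and the
#'   `relevances` matrix.
#' @export
stability_analysis <- function(dataset, config = pipeline_config(),
                               schema = c("rsss", "cv"), n_splits = 100L,
                               k = 10L, repeats = 20L, seed = 1L) {
  schema <- match.arg(schema)
  dataset <- binary_subset(dataset)
  y <- crc_labels(dataset)
  plan <- switch(schema,
    rsss = rsss_splits(y, n_splits = n_splits, seed = seed),
    cv = cv_splits(y, k = k, repeats = repeats, seed = seed)
  )
  M <- length(plan$splits)
  d <- n_features(dataset)
  Z <- matrix(0L, nrow = M, ncol = d,
              dimnames = list(NULL, dataset$matrix$feature_ids))
  R <- matrix(0, nrow = d, ncol = M,
              dimnames = list(dataset$matrix$feature_ids, NULL))
  for (s in seq_len(M)) {
    train <- subset_dataset(dataset, samples = plan$splits[[s]]$train)
    fit <- fit_pipeline(train, config)
    # record what the selection stage actually selected; with
    # on_empty = "all" the model may be fitted on everything, but an empty
    # selection must enter the stability statistics as empty
    if (!is.null(fit$selection)) {
      Z[s, ] <- as.integer(fit$selection$mask)
    } else {
      Z[s, fit$features] <- 1L
    }
    R[, s] <- pipeline_relevance(fit)
  }
  list(
    selection = nogueira_stability(Z),
    rank = rank_stability(R),
    selection_matrix = Z,
    relevances = R,
    schema = schema
  )
}
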