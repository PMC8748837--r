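# The risk-ordering test: do predicted CRC probabilities of condition
# groups the model never trained on rank as
# healthy < small adenoma < adenoma < tumor?

#' One-sided Mann-Whitney rank test
#'
#' Tests the alternative that `x` is stochastically smaller than `y`. Ties
#' are mid-ranked. For combined sample sizes up to 12 the p-value is
#' computed by exact enumeration of all group assignments (correct under
#' ties); otherwise a normal approximation with tie and continuity
#' correction is used.
#'
#' @param x,y Non-empty numeric samples (`x` the putatively smaller group).
#' @return One-sided p-value.
#' @export
mann_whitney_one_sided <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  m <- length(x)
  n <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)  # midranks
  U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
  if (m + n <= 12L) {
    combos <- combn(m + n, m)
    U_perm <- colSums(matrix(rk[combos], nrow = m)) - m * (m + 1) / 2
    mean(U_perm <= U_obs)
  } else {
    N <- m + n
    ties <- table(pooled)
    sigma2 <- (m * n / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(1)  # all values identical: no evidence
    z <- (U_obs - m * n / 2 + 0.5) / sqrt(sigma2)
    pnorm(z)
  }
}

#' Comparison specifications for the risk-ordering test
#'
#' The default set follows the radar-plot labels: adenoma < tumor,
#' healthy < adenoma, healthy < small adenoma, small adenoma < adenoma,
#' healthy < tumor. The direction of the small-adenoma-vs-healthy
#' comparison is ambiguous in the source material, so it is configurable
#' rather than silently chosen.
#'
#' @param small_adenoma_direction `"healthy_less"` (default: tests
#'   healthy < small adenoma) or `"small_less"` (tests
#'   small adenoma < healthy).
#' @return Data frame with columns `lesser`, `greater`, `label`.
#' @export
default_comparisons <- function(small_adenoma_direction = c("healthy_less",
                                                            "small_less")) {
  dir <- match.arg(small_adenoma_direction)
  hs <- if (dir == "healthy_less") {
    c("healthy", "small_adenoma", "H<S")
  } else {
    c("small_adenoma", "healthy", "S<H")
  }
  out <- rbind(
    c("adenoma", "crc", "A<T"),
    c("healthy", "adenoma", "H<A"),
    hs,
    c("small_adenoma", "adenoma", "S<A"),
    c("healthy", "crc", "H<T")
  )
  data.frame(lesser = out[, 1L], greater = out[, 2L], label = out[, 3L],
             stringsAsFactors = FALSE)
}

#' Learning / validation / test partition for the adenoma analysis
#'
#' All non-comorbid healthy and CRC samples form the training pool, which is
#' split (stratified by condition) into learning and validation sets of 0.7
#' and 0.3 of its size. Every remaining sample — adenomas, small adenomas,
#' other conditions, and comorbid healthy/CRC — goes to the test set, so
#' validation and test are both unseen by the fitted model.
#'
#' @param dataset A `profile_dataset` containing adenoma samples.
#' @param seed Integer seed for the random split.
#' @param learning_fraction Fraction of the pool used for learning
#'   (default 0.7).
#' @return List of sample-id vectors `learning`, `validation`, `test`
#'   (pairwise disjoint, union = all samples).
#' @export
adenoma_partition <- function(dataset, seed = 1L, learning_fraction = 0.7) {
  meta <- dataset$metadata
  if (!any(meta$condition %in% c("adenoma", "small_adenoma"))) {
    stop("no adenoma samples in the dataset")
  }
  eligible <- meta$condition %in% c("healthy", "crc") & !meta$comorbidity
  pool_ids <- meta$sample_id[eligible]
  pool_cond <- meta$condition[eligible]
  learning <- withr::with_seed(seed, {
    unlist(lapply(unique(pool_cond), function(cls) {
      ids <- pool_ids[pool_cond == cls]
      sample(ids, round(length(ids) * learning_fraction))
    }))
  })
  validation <- setdiff(pool_ids, learning)
  test <- setdiff(meta$sample_id, pool_ids)
  list(learning = learning, validation = validation, test = test)
}

#' Repeated risk-ordering hit-ratio test
#'
#' Per repeat: draw a fresh [adenoma_partition()], fit the pipeline on the
#' learning set, and predict P(crc) for the validation and test samples.
#' Healthy and CRC probabilities are taken from the validation split (unseen
#' but in-distribution); adenoma, small adenoma and other conditions come
#' from the test split. Each comparison then runs a one-sided Mann-Whitney
#' test that the lesser group's probabilities are stochastically smaller; a
#' repeat scores a hit when `p < alpha`. A repeat with an empty group is
#' skipped for that comparison (with adjusted denominator and a warning).
#'
#' @param dataset A multi-condition `profile_dataset` (typically the
#'   concatenation of all projects).
#' @param config A [pipeline_config()].
#' @param comparisons Data frame as produced by [default_comparisons()].
#' @param n_repeats Number of repeats (default 100).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed.
#' @return Object of class `hit_ratio_report`: per-comparison `hit_ratio`,
#'   `n_hits`, `n_effective`, plus `n_repeats`, `alpha`, `seed`.
#' @export
run_hit_ratio_test <- function(dataset, config = pipeline_config(),
                               comparisons = default_comparisons(),
                               n_repeats = 100L, alpha = 0.05, seed = 1L) {
  if (!nrow(comparisons)) stop("comparisons must be non-empty")
  meta <- dataset$metadata
  hits <- setNames(integer(nrow(comparisons)), comparisons$label)
  n_eff <- setNames(integer(nrow(comparisons)), comparisons$label)
  for (r in seq_len(n_repeats)) {
    part <- adenoma_partition(dataset, seed = seed + r)
    fit <- fit_pipeline(
      subset_dataset(dataset, samples = part$learning), config
    )
    unseen <- c(part$validation, part$test)
    probs <- predict_proba(fit, subset_dataset(dataset, samples = unseen))
    cond_of <- setNames(meta$condition, meta$sample_id)[unseen]
    in_validation <- unseen %in% part$validation
    group_probs <- function(cond) {
      # healthy/crc distributions come from validation only
      if (cond %in% c("healthy", "crc")) {
        probs[cond_of == cond & in_validation]
      } else {
        probs[cond_of == cond & !in_validation]
      }
    }
    for (i in seq_len(nrow(comparisons))) {
      lesser <- group_probs(comparisons$lesser[i])
      greater <- group_probs(comparisons$greater[i])
      if (!length(lesser) || !length(greater)) {
        warning("repeat ", r, ": empty group for comparison ",
                comparisons$label[i], "; skipped")
        next
      }
      n_eff[i] <- n_eff[i] + 1L
      if (mann_whitney_one_sided(lesser, greater) < alpha) {
        hits[i] <- hits[i] + 1L
      }
    }
  }
  structure(
    list(
      comparisons = comparisons$label,
      hit_ratio = ifelse(n_eff > 0, hits / n_eff, NaN),
      n_hits = hits, n_effective = n_eff,
      n_repeats = n_repeats, alpha = alpha, seed = seed
    ),
    class = "hit_ratio_report"
  )
}
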