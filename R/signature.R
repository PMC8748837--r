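# Consensus signature across LOPO runs, permutation significance of the
# validation score, and metabolite-level roll-up of KO relevance scores.

#' Consensus signature across LOPO runs
#'
#' Each run's relevance vector is min-max rescaled to `[0, 1]`, the rescaled
#' scores are summed across runs, and the sum is divided by
#' `(p - nz(i) + 1)`, where `p` is the number of projects (= runs) and
#' `nz(i)` the number of runs in which feature `i` has non-zero relevance.
#' A feature that fails the FDR selection in a run enters that run with
#' relevance 0; a feature with zero relevance in every run scores 0.
#'
#' @param relevance_runs Numeric matrix, features x runs (one column per
#'   LOPO run), or list of equal-length vectors.
#' @param p Number of projects; must equal the number of runs (default).
#' @param eps Threshold below which a relevance counts as zero (default 0,
#'   i.e. strictly positive counts as non-zero).
#' @return Object of class `consensus_signature`: `score` (>= 0 per
#'   feature), `nz`, `p`, `feature_ids`, and the `rescaled` matrix.
#' @export
consensus_signature <- function(relevance_runs, p = ncol(relevance_runs),
                                eps = 0) {
  if (is.list(relevance_runs)) relevance_runs <- do.call(cbind, relevance_runs)
  stopifnot(is.matrix(relevance_runs))
  if (ncol(relevance_runs) != p) {
    stop("run count (", ncol(relevance_runs), ") must equal p (", p, ")")
  }
  if (any(relevance_runs < 0)) stop("relevances must be nonnegative")
  rescaled <- apply(relevance_runs, 2L, function(x) {
    rng <- range(x)
    if (rng[1L] == rng[2L]) {
      warning("all-zero (constant) relevance run contributes zeros")
      return(rep(0, length(x)))
    }
    (x - rng[1L]) / (rng[2L] - rng[1L])
  })
  nz <- rowSums(relevance_runs > eps)
  score <- rowSums(rescaled) / (p - nz + 1)
  structure(
    list(
      score = setNames(score, rownames(relevance_runs)),
      nz = setNames(nz, rownames(relevance_runs)),
      p = p,
      feature_ids = rownames(relevance_runs),
      rescaled = rescaled
    ),
    class = "consensus_signature"
  )
}

#' Support of a consensus signature
#'
#' @param signature A [consensus_signature()].
#' @param eps Strictly-positive threshold.
#' @return Character vector of feature ids with score above `eps`.
#' @export
signature_support <- function(signature, eps = 0) {
  signature$feature_ids[signature$score > eps]
}

#' Add-one permutation p-value
#'
#' `p = (#\{perm >= observed\} + 1) / (B + 1)`; with `B = 100` the best
#' attainable p-value is 1/101 and the worst is 1.
#'
#' @param observed Observed (unpermuted) score.
#' @param perm_scores Numeric vector of permutation scores.
#' @return p-value in `[1/(B+1), 1]`.
#' @export
permutation_pvalue <- function(observed, perm_scores) {
  B <- length(perm_scores)
  if (B < 1L) stop("need at least one permutation score")
  (sum(perm_scores >= observed) + 1) / (B + 1)
}

#' Permutation significance of the validated score on a fixed signature
#'
#' The pipeline's feature set is fixed to the consensus-signature support;
#' the observed score is the mean AUROC of the validation design with the
#' true labels, and the null distribution is obtained by refitting after
#' randomly permuting the condition labels, `B` times.
#'
#' @param dataset A `profile_dataset` (restricted internally to healthy/crc).
#' @param signature_support Non-empty character vector of feature ids.
#' @param config A [pipeline_config()].
#' @param B Number of permutations (default 100).
#' @param mode Validation design scored inside the test: `"cv"` (default,
#'   repeated k-fold on the pooled samples) or `"olopo"`.
#' @param k,repeats CV parameters for `mode = "cv"`.
#' @param seed Integer seed.
#' @return Object of class `permutation_test_result`: `observed`,
#'   `perm_scores` (length `B`), `p_value`, `B`.
#' @export
permutation_significance <- function(dataset, signature_support,
                                     config = pipeline_config(), B = 100L,
                                     mode = c("cv", "olopo"), k = 10L,
                                     repeats = 10L, seed = 1L) {
  mode <- match.arg(mode)
  if (B < 1L) stop("B must be >= 1")
  if (!length(signature_support)) stop("signature support is empty")
  dataset <- binary_subset(dataset)
  cv_config <- config
  cv_config$select <- FALSE  # features fixed to the support; selection off
  score_fun <- function(ds, seed_offset) {
    if (mode == "cv") {
      repeated_cv(ds, cv_config, k = k, repeats = repeats,
                  seed = seed + seed_offset)$mean
    } else {
      mean(olopo(ds, config, external_mask = signature_support)$auroc,
           na.rm = TRUE)
    }
  }
  ds_fixed <- if (mode == "cv") {
    subset_dataset(dataset, features = signature_support)
  } else {
    dataset
  }
  observed <- score_fun(ds_fixed, 0L)
  perm_scores <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      ds_b <- ds_fixed
      ds_b$metadata$condition <- sample(ds_b$metadata$condition)
      score_fun(ds_b, b)
    }, numeric(1L))
  })
  structure(
    list(
      observed = observed, perm_scores = perm_scores,
      p_value = permutation_pvalue(observed, perm_scores),
      B = B, mode = mode, seed = seed
    ),
    class = "permutation_test_result"
  )
}

#' Metabolite-level scores from a KO signature
#'
#' Rolls per-KO consensus scores up to compounds:
#' `score(compound) = sum over mapped KOs of signature score(KO)`; KOs
#' absent from the signature contribute 0.
#'
#' @param signature A [consensus_signature()] over KEGG KO features.
#' @param compound_to_ko A data frame with columns `compound_id` and `ko_id`
#'   (one row per compound-KO link), e.g. read from a user-supplied TSV.
#' @return Named numeric vector of per-compound scores.
#' @export
metabolite_scores <- function(signature, compound_to_ko) {
  stopifnot(inherits(signature, "consensus_signature"))
  if (!all(c("compound_id", "ko_id") %in% names(compound_to_ko))) {
    stop("map needs columns compound_id and ko_id")
  }
  if (nrow(compound_to_ko) == 0L) stop("compound-to-KO map is empty")
  ko_score <- signature$score
  per_link <- ifelse(
    compound_to_ko$ko_id %in% names(ko_score),
    ko_score[compound_to_ko$ko_id], 0
  )
  vapply(split(per_link, compound_to_ko$compound_id), sum, numeric(1L))
}
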