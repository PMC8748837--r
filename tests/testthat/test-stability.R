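test_that("RSSS splits are stratified half-samples covering every sample", {
  y <- rep(c(0, 1), each = 50)
  plan <- rsss_splits(y, n_splits = 20, seed = 5)
  expect_length(plan$splits, 20L)
  for (s in plan$splits) {
    expect_length(s$train, 50L)
    expect_setequal(c(s$train, s$test), seq_len(100))
    expect_length(intersect(s$train, s$test), 0L)
    # stratification: 25 of each class in training
    expect_equal(sum(y[s$train]), 25)
  }
  plan2 <- rsss_splits(y, n_splits = 20, seed = 6)
  expect_false(identical(plan$splits, plan2$splits))
  expect_error(rsss_splits(c(0, 1), n_splits = 5), "at least 4")
})

test_that("Nogueira stability hits its analytic endpoints", {
  # identical selections -> exactly 1, degenerate CI
  Z <- matrix(0L, 100, 50)
  Z[, 1:10] <- 1L
  res <- nogueira_stability(Z)
  expect_equal(res$score, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
  expect_equal(unname(res$thresholds), c(0.4, 0.7))

  # hand-computed opposite pair: mean s^2 = 0.5, denominator 0.25 -> -1
  Z2 <- rbind(c(1L, 0L), c(0L, 1L))
  expect_equal(nogueira_stability(Z2)$score, -1)

  expect_error(nogueira_stability(matrix(0L, 5, 4)), "no")
  expect_error(nogueira_stability(matrix(1L, 5, 4)), "all")
  expect_error(nogueira_stability(Z[1, , drop = FALSE]), "at least 2")
})

test_that("random uniform selections score near zero and the CI brackets the score", {
  scores <- vapply(1:50, function(s) {
    Z <- withr::with_seed(s, t(replicate(30, {
      z <- integer(40); z[sample.int(40, 8)] <- 1L; z
    })))
    res <- nogueira_stability(Z)
    expect_lte(res$ci_low, res$score)
    expect_gte(res$ci_high, res$score)
    res$score
  }, numeric(1L))
  se <- sd(scores) / sqrt(length(scores))
  expect_lt(abs(mean(scores)), 3 * se + 0.01)
})

test_that("stability is invariant to row and column permutations", {
  Z <- withr::with_seed(9, matrix(rbinom(20 * 15, 1, 0.3), 20, 15))
  if (any(rowSums(Z) == 0)) Z[rowSums(Z) == 0, 1] <- 1L
  ref <- nogueira_stability(Z)$score
  expect_equal(nogueira_stability(Z[sample(20), ])$score, ref)
  expect_equal(nogueira_stability(Z[, sample(15)])$score, ref)
})

test_that("hwt endpoints: self-agreement 1, reversal -1, symmetry, bounds", {
  r <- 50:1
  expect_equal(hwt(r, r), 1)
  expect_equal(hwt(r, rev(r)), -1)
  set.seed(13)
  for (i in 1:20) {
    a <- runif(12)
    b <- runif(12)
    expect_equal(hwt(a, b), hwt(b, a))
    expect_true(abs(hwt(a, b)) <= 1 + 1e-12)
  }
  expect_error(hwt(1:3, 1:4), "length mismatch")
})

test_that("hwt agrees with the explicit pair-enumeration oracle and a reference implementation", {
  # frozen values from scipy.stats.weightedtau (additive hyperbolic
  # weigher, rank-averaged) on tie-free fixtures
  a1 <- c(5, 3, 8, 1, 7, 2, 6, 4)
  b1 <- c(8, 6, 7, 2, 5, 1, 3, 4)
  expect_equal(hwt(a1, b1), 0.4173080533133096, tolerance = 1e-12)

  ident <- 10:1
  top_swap <- c(9, 10, 8, 7, 6, 5, 4, 3, 2, 1)
  bottom_swap <- c(10, 9, 8, 7, 6, 5, 4, 3, 1, 2)
  expect_equal(hwt(ident, top_swap), 0.8861942826175315, tolerance = 1e-12)
  expect_equal(hwt(ident, bottom_swap), 0.9839828990350601, tolerance = 1e-12)
  # a top-of-rank discrepancy costs strictly more than a tail discrepancy
  expect_lt(hwt(ident, top_swap), hwt(ident, bottom_swap))

  # enumeration oracle on all permutations vs the identity, n = 4 and 5
  for (n in 4:5) {
    base <- as.numeric(n:1)
    for (p in all_permutations(n)) {
      pv <- as.numeric(p)
      expect_equal(hwt(base, base[pv]), hwt_oracle(base, base[pv]),
                   tolerance = 1e-12)
    }
  }
  # ties: oracle and implementation agree under midrank weighting
  set.seed(14)
  for (i in 1:10) {
    a <- sample(1:4, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    expect_equal(hwt(a, b), hwt_oracle(a, b), tolerance = 1e-12)
  }
})

test_that("rank stability summarizes pairwise hwt across splits", {
  R <- matrix(rep(c(5, 4, 3, 2, 1), 4), ncol = 4)
  res <- rank_stability(R)
  expect_equal(res$mean, 1)
  expect_equal(res$q25, 1)
  expect_equal(res$q75, 1)
  expect_length(res$values, choose(4, 2))

  set.seed(15)
  Rr <- matrix(runif(40 * 12), 40, 12)
  rr <- rank_stability(Rr)
  se <- sd(rr$values) / sqrt(length(rr$values))
  expect_lt(abs(rr$mean), 3 * se + 0.05)
  # matches direct pairwise hwt
  expect_equal(rr$values[1], hwt(Rr[, 1], Rr[, 2]))

  expect_error(rank_stability(R[, 1, drop = FALSE]), "at least 2")
})

test_that("the stability driver produces consistent selection and rank summaries", {
  gen <- tiny_dataset(seed = 51)
  res <- stability_analysis(gen$dataset, fast_config(), schema = "rsss",
                            n_splits = 10, seed = 2)
  expect_s3_class(res$selection, "stability_result")
  expect_s3_class(res$rank, "rank_stability_result")
  expect_equal(dim(res$selection_matrix), c(10L, 60L))
  expect_true(all(res$selection_matrix %in% 0:1))
  expect_equal(dim(res$relevances), c(60L, 10L))
  # strong planted signal: selection is highly stable and ranks agree
  expect_gt(res$selection$score, 0.7)
  expect_gt(res$rank$mean, 0.5)

  # CV schema: k x repeats training sets become the splits
  res_cv <- stability_analysis(gen$dataset, fast_config(), schema = "cv",
                               k = 4, repeats = 2, seed = 2)
  expect_equal(nrow(res_cv$selection_matrix), 8L)
})

test_that("a low-depth cohort destabilizes selection and ranking", {
  base <- tiny_config(seed = 52, n_projects = 1L,
                      samples_per_condition = c(healthy = 30L, crc = 30L))
  deep <- generate_dataset(base)
  shallow_cfg <- base
  shallow_cfg$low_depth_project <- 1L
  shallow_cfg$depth_factor <- 0.15
  shallow_cfg$low_depth_zero_inflation <- 0.5
  shallow <- generate_dataset(shallow_cfg)
  cfg <- fast_config(on_empty = "all")
  s_deep <- stability_analysis(deep$dataset, cfg, n_splits = 8, seed = 3)
  s_shallow <- stability_analysis(shallow$dataset, cfg, n_splits = 8, seed = 3)
  expect_gt(s_deep$selection$score, s_shallow$selection$score)
  expect_gt(s_deep$rank$mean, s_shallow$rank$mean)
})
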