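test_that("one-sided Mann-Whitney matches exact enumeration and wilcox.test", {
  expect_equal(mann_whitney_one_sided(c(1, 2), c(3, 4)), 1 / 6)
  # identical samples: no evidence for the one-sided alternative
  expect_gte(mann_whitney_one_sided(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(mann_whitney_one_sided(numeric(0), 1:3), "non-empty")

  set.seed(71)
  # exact path (combined n <= 12), with and without ties, vs enumeration
  for (i in 1:20) {
    m <- sample(2:5, 1); n <- sample(2:5, 1)
    x <- sample(1:6, m, replace = TRUE)
    y <- sample(1:6, n, replace = TRUE)
    expect_equal(mann_whitney_one_sided(x, y), mw_oracle(x, y))
  }
  # tie-free exact path agrees with stats::wilcox.test(exact)
  for (i in 1:10) {
    z <- sample(100, 10)
    x <- z[1:4]; y <- z[5:10]
    expect_equal(mann_whitney_one_sided(x, y),
                 stats::wilcox.test(x, y, alternative = "less",
                                    exact = TRUE)$p.value)
  }
  # large-sample normal path tracks wilcox.test's corrected approximation
  x <- rnorm(30); y <- rnorm(40) + 0.5
  expect_equal(mann_whitney_one_sided(x, y),
               stats::wilcox.test(x, y, alternative = "less",
                                  exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("swapping the groups maps the exact p-value to the opposite tail", {
  set.seed(72)
  for (i in 1:15) {
    x <- sample(1:5, 4, replace = TRUE)
    y <- sample(1:5, 4, replace = TRUE)
    p_xy <- mann_whitney_one_sided(x, y)
    p_yx <- mann_whitney_one_sided(y, x)
    # P(U <= u) + P(U' <= u') = 1 + P(U == u) under enumeration, where the
    # equality mass is that of the observed statistic
    m <- length(x)
    rk <- rank(c(x, y))
    U_obs <- sum(rk[seq_len(m)]) - m * (m + 1) / 2
    combos <- combn(8, m)
    U_all <- apply(combos, 2, function(idx) sum(rk[idx]) - m * (m + 1) / 2)
    expect_equal(p_xy + p_yx, 1 + mean(U_all == U_obs), tolerance = 1e-12)
  }
})

test_that("the adenoma partition follows the 0.7/0.3 rule and the comorbidity rule", {
  set.seed(73)
  vals <- matrix(rexp(130 * 5), 130, 5)
  conds <- c(rep("healthy", 50), rep("crc", 50), rep("adenoma", 15),
             rep("small_adenoma", 10), rep("other", 5))
  comorb <- rep(FALSE, 130)
  comorb[c(1, 51)] <- TRUE  # one comorbid healthy, one comorbid crc
  ds <- dataset_from_matrix(vals, conds, comorbidity = comorb)
  part <- adenoma_partition(ds, seed = 1)
  # pool = 98 non-comorbid healthy+crc; leaning on per-class rounding
  expect_length(part$learning, round(49 * 0.7) * 2)
  expect_length(part$validation, 98 - length(part$learning))
  expect_length(part$test, 32)
  expect_setequal(c(part$learning, part$validation, part$test),
                  ds$metadata$sample_id)
  comorb_ids <- ds$metadata$sample_id[comorb]
  expect_true(all(comorb_ids %in% part$test))

  # balanced 100-sample pool splits exactly 70/30
  ds100 <- dataset_from_matrix(
    matrix(rexp(110 * 3), 110, 3),
    c(rep("healthy", 50), rep("crc", 50), rep("adenoma", 10))
  )
  p100 <- adenoma_partition(ds100, seed = 2)
  expect_length(p100$learning, 70L)
  expect_length(p100$validation, 30L)

  no_adenoma <- dataset_from_matrix(matrix(rexp(20), 10, 2),
                                    rep(c("healthy", "crc"), 5))
  expect_error(adenoma_partition(no_adenoma, seed = 1), "no adenoma")
})

test_that("the default comparisons follow the radar labels with a direction switch", {
  cmp <- default_comparisons()
  expect_equal(cmp$label, c("A<T", "H<A", "H<S", "S<A", "H<T"))
  expect_equal(cmp$lesser[cmp$label == "H<S"], "healthy")
  cmp2 <- default_comparisons("small_less")
  expect_equal(cmp2$label[3], "S<H")
  expect_equal(cmp2$lesser[3], "small_adenoma")
})

test_that("ordered planted effects produce the graded hit-ratio pattern", {
  gen <- tiny_dataset(seed = 74)
  hr <- run_hit_ratio_test(gen$dataset, fast_config(), n_repeats = 10,
                           seed = 3)
  ratios <- setNames(hr$hit_ratio, hr$comparisons)
  expect_equal(unname(ratios["H<T"]), 1)
  expect_gte(ratios[["H<A"]], 0.9)
  expect_true(all(hr$n_effective == 10L))

  # CRC-only effects: the adenoma comparison collapses to the null level
  gent <- tiny_dataset(seed = 74, mode = "taxonomic")
  hrt <- run_hit_ratio_test(gent$dataset, fast_config(), n_repeats = 10,
                            seed = 3)
  rt <- setNames(hrt$hit_ratio, hrt$comparisons)
  expect_equal(unname(rt["H<T"]), 1)
  expect_lte(rt[["H<A"]], 0.3)
})

test_that("missing condition groups are skipped with adjusted denominators", {
  gen <- tiny_dataset(
    seed = 75,
    samples_per_condition = c(healthy = 15L, crc = 15L, adenoma = 5L)
  )
  w <- capture_warnings(
    hr <- run_hit_ratio_test(gen$dataset, fast_config(), n_repeats = 2,
                             seed = 1)
  )
  expect_true(any(grepl("empty group", w)))
  ratios <- setNames(hr$n_effective, hr$comparisons)
  expect_equal(unname(ratios["H<S"]), 0L)
  expect_true(is.nan(hr$hit_ratio[hr$comparisons == "H<S"]))
  expect_equal(unname(ratios["H<T"]), 2L)
})

test_that("raising the adenoma effect raises the H<A hit ratio", {
  run_ratio <- function(adenoma_mult, seed) {
    gen <- generate_dataset(tiny_config(
      seed = seed,
      effect_profile = c(healthy = 1, small_adenoma = 1,
                         adenoma = adenoma_mult, crc = 6)
    ))
    hr <- run_hit_ratio_test(gen$dataset, fast_config(), n_repeats = 8,
                             seed = seed)
    hr$hit_ratio[hr$comparisons == "H<A"]
  }
  low <- mean(vapply(1:3, function(s) run_ratio(1, s), numeric(1L)))
  high <- mean(vapply(1:3, function(s) run_ratio(3.5, s), numeric(1L)))
  expect_gt(high, low)
  expect_gte(high, 0.8)
  expect_lte(low, 0.4)
})
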