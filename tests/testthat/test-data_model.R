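test_that("profile TSV parsing handles the standard layout and degenerate files", {
  path <- write_profile_fixture(c(
    "feature_id\tS1\tS2",
    "K00001\t0\t2",
    "K00002\t1\t3"
  ))
  pm <- read_profile_tsv(path, "kegg")
  expect_equal(pm$sample_ids, c("S1", "S2"))
  expect_equal(pm$feature_ids, c("K00001", "K00002"))
  expect_equal(unname(pm$values), matrix(c(0, 2, 1, 3), nrow = 2))
  expect_equal(pm$namespace, "kegg")

  empty <- write_profile_fixture("feature_id\tS1\tS2")
  expect_error(read_profile_tsv(empty, "kegg"), "no samples")

  dup <- write_profile_fixture(c(
    "feature_id\tS1", "K01846\t1", "K01846\t2"
  ))
  expect_error(read_profile_tsv(dup, "kegg"), "K01846")

  neg <- write_profile_fixture(c(
    "feature_id\tS1\tS2", "K00001\t1\t2", "K00002\t-3\t4"
  ))
  expect_error(read_profile_tsv(neg, "kegg"), "S1.*K00002")

  txt <- write_profile_fixture(c(
    "feature_id\tS1\tS2", "K00001\t1\tabc"
  ))
  expect_error(read_profile_tsv(txt, "kegg"), "abc")
})

test_that("profile matrix and metadata invariants are enforced", {
  vals <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("f1", "f2")))
  expect_s3_class(profile_matrix(vals, "kegg"), "profile_matrix")
  bad <- vals
  rownames(bad) <- c("a", "a")
  expect_error(profile_matrix(bad, "kegg"), "duplicate sample id: a")

  meta <- data.frame(sample_id = c("a", "b"), project_id = "P1",
                     condition = c("healthy", "crc"), comorbidity = FALSE)
  expect_s3_class(sample_metadata(meta), "sample_metadata")
  meta_bad <- meta
  meta_bad$condition[1] <- "tumour"
  expect_error(sample_metadata(meta_bad), "vocabulary")

  # dataset requires a 1-1 sample correspondence, and reorders metadata
  ds <- profile_dataset(profile_matrix(vals, "kegg"), meta[c(2, 1), ])
  expect_equal(ds$metadata$sample_id, c("a", "b"))
  expect_error(
    profile_dataset(profile_matrix(vals, "kegg"),
                    data.frame(sample_id = c("a", "c"), project_id = "P1",
                               condition = "healthy", comorbidity = FALSE)),
    "disagree"
  )
})

test_that("metadata TSV round-trips", {
  meta <- sample_metadata(data.frame(
    sample_id = c("a", "b"), project_id = c("P1", "P2"),
    condition = c("adenoma", "crc"), comorbidity = c(FALSE, TRUE)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metadata_tsv(meta, path)
  back <- read_metadata_tsv(path)
  expect_equal(as.data.frame(back), as.data.frame(meta))
})

test_that("concat unions features with zero fill and rejects invalid unions", {
  m1 <- matrix(1:4, 2, dimnames = list(c("s1", "s2"), c("A", "B")))
  m2 <- matrix(5:8, 2, dimnames = list(c("s3", "s4"), c("B", "C")))
  mk <- function(m, proj) dataset_from_matrix(
    m, conditions = c("healthy", "crc"), project = proj
  )
  d1 <- mk(m1, "P1")
  d2 <- mk(m2, "P2")
  cc <- concat_datasets(list(d1, d2))
  expect_equal(n_samples(cc), 4L)
  expect_setequal(cc$matrix$feature_ids, c("A", "B", "C"))
  expect_equal(cc$matrix$values["s1", "C"], 0)
  expect_equal(cc$matrix$values["s4", "A"], 0)
  expect_equal(cc$matrix$values["s3", "B"], 5)

  expect_error(concat_datasets(list(d1, d1)), "duplicate sample id")
  d2tax <- dataset_from_matrix(m2, c("healthy", "crc"), "P2",
                               namespace = "taxonomic")
  expect_error(concat_datasets(list(d1, d2tax)), "mixed namespaces")
})

test_that("concat is associative up to row/column ordering", {
  set.seed(42)
  mats <- lapply(1:3, function(i) {
    feats <- sample(LETTERS[1:6], 4)
    m <- matrix(runif(8), 2, dimnames = list(
      paste0("s", i, 1:2), feats[1:4]
    ))
    dataset_from_matrix(m, c("healthy", "crc"), paste0("P", i))
  })
  left <- concat_datasets(list(concat_datasets(mats[1:2]), mats[[3]]))
  right <- concat_datasets(list(mats[[1]], concat_datasets(mats[2:3])))
  f <- sort(left$matrix$feature_ids)
  s <- sort(left$matrix$sample_ids)
  expect_equal(left$matrix$values[s, f], right$matrix$values[s, f])
})

test_that("report JSON round-trips all report types, including NaN -> null -> NaN", {
  path <- withr::local_tempfile(fileext = ".json")

  stab <- structure(
    list(score = 1, ci_low = 1, ci_high = 1,
         thresholds = c(bad = 0.4, near_perfect = 0.7),
         n_splits = 100L, n_features = 50L, alpha = 0.05),
    class = "stability_result"
  )
  write_report_json(stab, path)
  back <- read_report_json(path)
  expect_s3_class(back, "stability_result")
  expect_equal(back$score, 1)
  expect_equal(back$thresholds, stab$thresholds)

  # NaN scores serialize as null and come back as NaN
  stab$score <- NaN
  write_report_json(stab, path)
  expect_true(is.nan(read_report_json(path)$score))

  hr <- structure(
    list(comparisons = c("A<T", "H<A", "H<S", "S<A", "H<T"),
         hit_ratio = c(1, 0.97, 0.4, 0.93, 1),
         n_hits = c(100L, 97L, 40L, 93L, 100L),
         n_effective = rep(100L, 5), n_repeats = 100L, alpha = 0.05,
         seed = 1L),
    class = "hit_ratio_report"
  )
  write_report_json(hr, path)
  back <- read_report_json(path)
  expect_length(back$comparisons, 5L)
  expect_equal(back$hit_ratio, hr$hit_ratio)

  # matrix-valued fields keep dimnames
  cpm <- structure(
    list(auroc = matrix(c(0.9, NaN, 0.6, 0.8), 2,
                        dimnames = list(c("P1", "P2"), c("P1", "P2"))),
         projects = c("P1", "P2")),
    class = "cross_prediction_matrix"
  )
  write_report_json(cpm, path)
  back <- read_report_json(path)
  expect_equal(back$auroc, cpm$auroc)
  expect_true(is.nan(back$auroc["P2", "P1"]))
})
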