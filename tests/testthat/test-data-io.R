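make_om <- function(values, type = "mrna") {
  rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  omics_matrix(values, omics_type = type)
}

test_that("feature filter drops features strictly above the bad-fraction threshold", {
  vals <- matrix(1, 10, 3)
  vals[1:3, 1] <- 0        # 30% zeros -> removed
  vals[1:2, 2] <- NA       # 20% missing -> retained (rule is strictly >)
  m <- filter_features(make_om(vals))
  expect_equal(m$feature_ids, c("f02", "f03"))

  clean <- make_om(matrix(rnorm(30) + 10, 10, 3))
  expect_equal(filter_features(clean)$values, clean$values)
  expect_error(filter_features(make_om(matrix(0, 4, 2))), "all mrna features")
})

test_that("sample filter drops samples strictly above the bad-fraction threshold", {
  vals <- matrix(1, 4, 8)
  vals[1, 1:2] <- 0        # 25% -> removed
  suppressMessages(m <- filter_samples(make_om(vals)))
  expect_equal(m$sample_ids, c("S02", "S03", "S04"))
  clean <- make_om(matrix(1, 4, 8))
  expect_equal(filter_samples(clean)$values, clean$values)
})

test_that("filter order matters and the pipeline filters features first", {
  # f01 is 30% bad over all samples; sample S01 is 25% bad over all features.
  vals <- matrix(1, 10, 8)
  vals[1:3, 1] <- 0
  vals[1, 2] <- 0
  m <- make_om(vals)
  features_first <- suppressMessages(filter_samples(filter_features(m)))
  samples_first <- suppressMessages(filter_features(filter_samples(m)))
  # features-first: f01 removed, S01 then only 1/7 bad and survives
  expect_true("S01" %in% features_first$sample_ids)
  expect_false("f01" %in% features_first$feature_ids)
  # samples-first removes S01 -> outcomes differ
  expect_false("S01" %in% samples_first$sample_ids)
  expect_false(identical(dim(features_first$values), dim(samples_first$values)))

  gen <- generate_multiomics(synthetic_spec(
    n_samples = 30, block_widths = c(20, 10, 20), informative_per_block = c(3, 2, 3),
    missing_fraction = 0.03, zero_fraction = 0.03, seed = 11))
  d <- suppressMessages(preprocess_omics(gen$omics$mrna, gen$omics$mirna,
                                         gen$omics$methylation, gen$survival))
  expect_false(anyNA(d$matrix))
})

test_that("knn imputation fills with the mean of nearest observed features", {
  set.seed(5)
  vals <- matrix(rnorm(8 * 6), 8, 6)
  m <- make_om(vals)
  expect_identical(knn_impute(m)$values, m$values)   # no NA -> bitwise identity

  vals2 <- vals
  vals2[3, 2] <- NA
  m2 <- make_om(vals2)
  v2 <- m2$values
  imp <- knn_impute(m2, k = 100)   # k >= all features -> mean of all others
  expect_equal(imp$values[3, 2], mean(v2[3, -2]))
  # non-missing entries untouched, deterministic under repeated calls
  expect_equal(imp$values[-3, ], v2[-3, ])
  expect_identical(knn_impute(m2, k = 100)$values, imp$values)

  # brute-force oracle at k = 2: two nearest features by RMS difference
  imp2 <- knn_impute(m2, k = 2)
  d <- apply(v2[, -2, drop = FALSE], 2, function(col) mean((col - v2[, 2])^2, na.rm = TRUE))
  nn <- names(sort(d))[1:2]
  expect_equal(imp2$values[3, 2], mean(v2[3, nn]))
})

test_that("stacking intersects samples, preserves values and records blocks", {
  mk <- function(ids, p, type) {
    v <- matrix(seq_len(length(ids) * p), length(ids), p,
                dimnames = list(ids, paste0(type, seq_len(p))))
    omics_matrix(v, omics_type = type)
  }
  mrna <- mk(c("A", "B", "C"), 5, "mrna")
  mirna <- mk(c("B", "A"), 3, "mirna")
  meth <- mk(c("A", "B", "D"), 4, "methylation")
  surv <- survival_table(c("A", "B", "C"), c(10, 20, 30), c(1, 0, 1))
  d <- intersect_and_stack(mrna, mirna, meth, surv)
  expect_equal(d$sample_ids, c("A", "B"))
  expect_equal(ncol(d$matrix), 12)
  expect_equal(unname(lapply(d$blocks, range)),
               list(c(1L, 5L), c(6L, 8L), c(9L, 12L)))
  # values preserved through stacking
  expect_equal(unname(d$matrix["A", d$blocks$mirna]), unname(mirna$values["A", ]))
  expect_equal(unname(d$matrix["B", d$blocks$methylation]), unname(meth$values["B", ]))
  expect_equal(d$survival$time, c(10, 20))

  surv_dis <- survival_table(c("X", "Y"), c(1, 2), c(1, 1))
  expect_error(intersect_and_stack(mrna, mirna, meth, surv_dis), "no common samples")
})

test_that("unit-norm scaling normalises rows and is idempotent", {
  m <- matrix(c(3, 4, 0, 1), 2, 2, byrow = TRUE)
  out <- scale_unit_norm(m)
  expect_equal(out[1, ], c(0.6, 0.8))
  expect_equal(out[2, ], c(0, 1))
  set.seed(9)
  r <- matrix(rnorm(200), 20, 10)
  rs <- scale_unit_norm(r)
  expect_true(all(abs(sqrt(rowSums(rs^2)) - 1) < 1e-12))
  expect_equal(scale_unit_norm(rs), rs)
})

test_that("min-max scaling maps features onto [0,1] and is idempotent", {
  m <- cbind(c(2, 4, 6), c(7, 7, 7))
  out <- scale_minmax(m)
  expect_equal(out[, 1], c(0, 0.5, 1))
  expect_equal(out[, 2], c(0, 0, 0))   # constant feature -> 0
  set.seed(10)
  r <- matrix(rnorm(200), 20, 10)
  rs <- scale_minmax(r)
  expect_true(all(apply(rs, 2, min) == 0) && all(apply(rs, 2, max) == 1))
  expect_equal(scale_minmax(rs), rs)
})

test_that("matrices and clinical tables round-trip through TSV", {
  gen <- generate_multiomics(synthetic_spec(n_samples = 12, block_widths = c(6, 4, 5),
                                            informative_per_block = c(2, 1, 2), seed = 3))
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "mirna.tsv")
  write_omics_matrix(gen$omics$mirna, p)
  back <- read_omics_matrix(p, "mirna")
  expect_equal(back$values, gen$omics$mirna$values, tolerance = 1e-12)
  ps <- file.path(tmp, "clin.tsv")
  write_survival_table(gen$survival, ps)
  backs <- read_survival_table(ps)
  expect_equal(backs$time, gen$survival$time, tolerance = 1e-12)
  expect_equal(backs$event, gen$survival$event)
})
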