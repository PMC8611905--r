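test_that("two-step scaling applies median-norm then robust/unit-norm per block", {
  # block widths 3/2/3, constructed values
  mat <- cbind(c(2, 4, 8), matrix(1, 3, 2), matrix(2, 3, 2), matrix(5, 3, 3))
  mat[, 2] <- c(1, 2, 3)
  colnames(mat) <- paste0("f", 1:8)
  rownames(mat) <- paste0("S", 1:3)
  sv <- survival_table(paste0("S", 1:3), c(1, 2, 3), c(1, 1, 0))
  d <- multiomics_dataset(mat, list(mrna = 1:3, mirna = 4:5, methylation = 6:8), sv)
  out <- twostep_scale(d)
  # mrna feature 1: median-norm [2,4,8]/4 = [0.5,1,2]; robust: med 1, IQR 0.75
  expect_equal(unname(out$matrix[, 1]), (c(0.5, 1, 2) - 1) / 0.75)
  # mrna feature 2: [1,2,3]/2 -> robust -> [-1,0,1]
  expect_equal(unname(out$matrix[, 2]), c(-1, 0, 1))
  # miRNA block rows unit-norm within the block
  expect_true(all(abs(sqrt(rowSums(out$matrix[, 4:5]^2)) - 1) < 1e-12))
  # mRNA block medians ~ 0 after robust scaling
  fx <- get_fixture()
  sc <- twostep_scale(fx$dataset)
  med <- apply(sc$matrix[, sc$blocks$mrna], 2, median)
  expect_lt(max(abs(med)), 1e-10)
})

test_that("per-feature ANOVA matches t^2 = F and handles degenerate features", {
  set.seed(61)
  mat <- matrix(rnorm(40 * 12), 40, 12)
  colnames(mat) <- paste0("f", 1:12)
  lab <- rep(1:2, each = 20)
  tab <- anova_per_feature(mat, lab)
  for (j in 1:12) {
    tt <- stats::t.test(mat[lab == 1, j], mat[lab == 2, j], var.equal = TRUE)
    expect_equal(tab$f_statistic[j], unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(tab$p_value[j], tt$p.value, tolerance = 1e-10)
  }
  # also cross-checked against oneway.test on a three-group case
  lab3 <- rep(1:3, length.out = 40)
  tab3 <- anova_per_feature(mat, lab3)
  ow <- stats::oneway.test(mat[, 5] ~ factor(lab3), var.equal = TRUE)
  expect_equal(tab3$f_statistic[5], unname(ow$statistic), tolerance = 1e-10)

  mat2 <- cbind(const = rep(3, 40), sep = lab + rnorm(40, sd = 1e-4))
  tab2 <- anova_per_feature(mat2, lab)
  expect_equal(tab2$p_value[1], 1)
  expect_lt(tab2$p_value[2], 1e-20)
  expect_error(anova_per_feature(mat, c(1, rep(2, 39))), "at least 2 samples")

  # F is invariant to affine per-feature rescaling
  resc <- sweep(sweep(mat, 2, runif(12, 0.5, 3), "*"), 2, rnorm(12), "+")
  expect_equal(anova_per_feature(resc, lab)$f_statistic, tab$f_statistic,
               tolerance = 1e-8)
})

test_that("top-feature selection pools 10% then applies the Bonferroni cut", {
  set.seed(62)
  n <- 30
  mat <- matrix(rnorm(n * 420), n, 420)
  colnames(mat) <- paste0("m", 1:420)
  sv <- survival_table(paste0("S", 1:n), rexp(n, 0.01), rbinom(n, 1, 0.8))
  d <- multiomics_dataset(mat, list(mirna = 1:420), sv)
  lab <- rep(1:2, each = 15)
  mat[, 1:20] <- mat[, 1:20] + 3 * (lab - 1)   # 20 separated features
  d$matrix <- mat
  tab <- anova_per_feature(d, lab)
  tops <- top_features(tab)
  expect_lte(length(tops$mirna), 42)           # floor(0.10 * 420)
  expect_true(all(paste0("m", 1:20) %in% tops$mirna))

  tab_null <- tab
  tab_null$p_value <- 0.5
  tab_null$rank <- rank(tab_null$p_value, ties.method = "first")
  expect_length(top_features(tab_null)$mirna, 0)
})

test_that("planted informative features are recovered from truth labels", {
  fx <- get_fixture()
  sc <- twostep_scale(fx$dataset)
  tab <- anova_per_feature(sc, fx$truth$cluster_labels)
  tops <- top_features(tab)
  for (blk in names(fx$truth$informative_feature_ids)) {
    planted <- paste0(blk, ":", fx$truth$informative_feature_ids[[blk]])
    recall <- mean(planted %in% tops[[blk]])
    expect_gte(recall, 0.9)
    fdp <- mean(!(tops[[blk]] %in% planted))
    expect_lte(fdp, 0.2)
  }
})

test_that("consensus counts runs correctly and stays monotone", {
  sets <- lapply(1:10, function(i) {
    list(mrna = c("a", "b", if (i <= 7) "c", paste0("x", i)),
         mirna = c("m1"))
  })
  rep10 <- consensus(sets)
  expect_equal(unname(rep10$per_omics$mrna$counts), c(3L, 2L, 2L))
  expect_setequal(rep10$per_omics$mrna$robust, c("a", "b"))
  expect_false("c" %in% rep10$per_omics$mrna$robust)   # 7/10 counted at >=6 only
  expect_setequal(rep10$per_omics$mirna$robust, "m1")
  cts <- rep10$per_omics$mrna$counts
  expect_true(cts[1] >= cts[2] && cts[2] >= cts[3])
  expect_error(consensus(sets, n_runs = 8), "expected 8")

  disjoint <- lapply(1:10, function(i) list(mrna = paste0("only", i)))
  expect_equal(unname(consensus(disjoint)$per_omics$mrna$counts), c(0L, 0L, 0L))
})

test_that("novelty is the robust set difference against the other losses", {
  mk <- function(robust) {
    structure(list(per_omics = list(mrna = list(robust = robust,
                                                counts = c(0L, 0L, length(robust)))),
                   n_runs = 10, thresholds = c(6, 8, 10)),
              class = "consensus_report")
  }
  focal <- mk(c("a", "b", "c"))
  expect_setequal(novelty(focal, list(mk("b")))$mrna, c("a", "c"))
  expect_length(novelty(focal, list(mk(c("a", "b", "c", "d"))))$mrna, 0)
  expect_setequal(novelty(focal, list())$mrna, c("a", "b", "c"))
  expect_length(novelty(focal, list(focal))$mrna, 0)   # novelty against itself
})

test_that("z-score export is clipped, ordered by cluster, and zero for constants", {
  fx <- get_fixture()
  feats <- fx$dataset$feature_ids[c(1, 5, 400)]
  z <- zscore_matrix(fx$dataset, feats, fx$truth$cluster_labels)
  expect_true(all(z$matrix >= -3 & z$matrix <= 3))
  expect_true(!is.unsorted(z$labels))
  expect_equal(dim(z$matrix), c(3, 120))
  expect_error(zscore_matrix(fx$dataset, "nope", fx$truth$cluster_labels), "unknown feature")

  d <- fx$dataset
  d$matrix[, 1] <- 7
  zc <- zscore_matrix(d, d$feature_ids[1], fx$truth$cluster_labels)
  expect_true(all(zc$matrix == 0))
  big <- d
  big$matrix[1, 2] <- big$matrix[1, 2] + 100   # way over 3 SDs
  zb <- zscore_matrix(big, d$feature_ids[2], fx$truth$cluster_labels)
  expect_equal(max(zb$matrix), 3)
})
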