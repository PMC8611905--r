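## Discovery of the original omics features that differentiate clusters:
## two-step scaling, per-feature one-way ANOVA, top-fraction +
## Bonferroni-threshold selection, cross-run consensus and cross-loss
## novelty.

EPS_SCALE <- 1e-12

#' Two-step scaling before feature-level ANOVA
#'
#' Step 1: every omics block is median-norm scaled — each feature divided
#' by its median (epsilon-guarded; switchable to per-sample via
#' `median_axis`). Step 2: the mRNA and methylation blocks are
#' robust-scaled per feature (subtract median, divide by IQR,
#' epsilon-guarded), while the miRNA block is unit-norm scaled per sample
#' within the block.
#'
#' @param d a `multiomics_dataset` (the preprocessed matrix, before any
#'   model-specific scaling).
#' @param median_axis `"feature"` (default) or `"sample"`: axis of the
#'   step-1 median normalisation.
#' @return the dataset with a rescaled matrix.
#' @export
twostep_scale <- function(d, median_axis = c("feature", "sample")) {
  stopifnot(inherits(d, "multiomics_dataset"))
  median_axis <- match.arg(median_axis)
  mat <- d$matrix
  assert_finite_matrix(mat, "dataset matrix")
  if (median_axis == "feature") {
    med <- apply(mat, 2, stats::median)
    med[abs(med) < EPS_SCALE] <- EPS_SCALE
    mat <- sweep(mat, 2, med, "/")
  } else {
    med <- apply(mat, 1, stats::median)
    med[abs(med) < EPS_SCALE] <- EPS_SCALE
    mat <- sweep(mat, 1, med, "/")
  }
  for (blk in names(d$blocks)) {
    idx <- d$blocks[[blk]]
    sub <- mat[, idx, drop = FALSE]
    if (blk == "mirna") {
      nrm <- sqrt(rowSums(sub^2))
      nrm[nrm == 0] <- 1
      mat[, idx] <- sub / nrm
    } else {
      med2 <- apply(sub, 2, stats::median)
      iqr <- apply(sub, 2, stats::IQR)
      iqr[iqr < EPS_SCALE] <- EPS_SCALE
      mat[, idx] <- sweep(sweep(sub, 2, med2), 2, iqr, "/")
    }
  }
  d$matrix <- mat
  d
}

#' One-way ANOVA of every feature across cluster labels
#'
#' Computes, per feature, the one-way F statistic and P-value for a
#' difference in means across the groups given by `labels`, and the rank of
#' each feature within its omics block by ascending P. Constant features
#' (or features with zero within- and between-group variance) get
#' `p_value = 1` so the ranking stays total.
#'
#' @param d a `multiomics_dataset` (typically after [twostep_scale]) or a
#'   plain matrix (then all features are reported as one block).
#' @param labels cluster labels; every group must have at least 2 samples.
#' @return an `anova_table` data.frame: `feature`, `omics_type`,
#'   `f_statistic`, `p_value`, `rank`.
#' @export
anova_per_feature <- function(d, labels) {
  if (inherits(d, "multiomics_dataset")) {
    mat <- d$matrix
    blocks <- d$blocks
  } else {
    mat <- as.matrix(d)
    blocks <- list(all = seq_len(ncol(mat)))
  }
  labels <- as.integer(as.factor(labels))
  sizes <- tabulate(labels)
  if (length(sizes) < 2) stopf("ANOVA needs at least 2 groups")
  if (any(sizes < 2)) stopf("every group must contain at least 2 samples")
  n <- nrow(mat)
  k <- length(sizes)
  G <- outer(labels, seq_len(k), "==") * 1
  group_means <- (t(G) %*% mat) / sizes       # k x p
  grand <- colMeans(mat)
  ssb <- colSums(sizes * sweep(group_means, 2, grand)^2)
  sst <- colSums(sweep(mat, 2, grand)^2)
  ssw <- pmax(sst - ssb, 0)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- stats::pf(f, k - 1, n - k, lower.tail = FALSE)
  degenerate <- !is.finite(f) | sst < EPS_SCALE
  f[degenerate] <- NA_real_
  p[degenerate] <- 1
  otype <- character(ncol(mat))
  for (blk in names(blocks)) otype[blocks[[blk]]] <- blk
  tab <- data.frame(feature = colnames(mat) %||% paste0("f", seq_len(ncol(mat))),
                    omics_type = otype, f_statistic = f, p_value = p,
                    stringsAsFactors = FALSE)
  tab$rank <- stats::ave(tab$p_value, tab$omics_type,
                         FUN = function(x) rank(x, ties.method = "first"))
  class(tab) <- c("anova_table", "data.frame")
  tab
}

#' Select top differentiating features per omics block
#'
#' Within each omics block, takes the `floor(top_fraction * n_features)`
#' features with the smallest ANOVA P-values and keeps only those below
#' `p_cut` (the Bonferroni threshold for the configured number of pipeline
#' runs, 0.05 / 10 = 0.005 by default).
#'
#' @param tab an `anova_table` from [anova_per_feature].
#' @param top_fraction fraction of each block to shortlist, default 0.10.
#' @param p_cut significance threshold applied after the shortlist.
#' @return named list (per omics type) of selected feature id vectors.
#' @export
top_features <- function(tab, top_fraction = 0.10, p_cut = 0.005) {
  stopifnot(inherits(tab, "anova_table"))
  out <- list()
  for (blk in unique(tab$omics_type)) {
    sub <- tab[tab$omics_type == blk, ]
    pool <- max(floor(top_fraction * nrow(sub)), 0)
    sel <- sub[sub$rank <= pool & sub$p_value < p_cut, ]
    out[[blk]] <- sel$feature[order(sel$rank)]
  }
  out
}

#' Cross-run consensus of top features
#'
#' Counts, per omics type, how many features recur in at least 60%, at
#' least 80%, and all of the runs (6, 8 and 10 runs at the default of ten
#' pipeline repetitions). A feature present in every run is *robust*.
#'
#' @param per_run_sets list of per-run outputs of [top_features] (one
#'   element per run).
#' @param n_runs expected number of runs; defaults to
#'   `length(per_run_sets)` and is checked against it.
#' @return a `consensus_report`: per omics type, `counts` (named vector at
#'   the three thresholds), `frequency` (per-feature run counts) and
#'   `robust` (feature ids present in all runs).
#' @export
consensus <- function(per_run_sets, n_runs = length(per_run_sets)) {
  if (length(per_run_sets) != n_runs) {
    stopf("expected %d runs, got %d", n_runs, length(per_run_sets))
  }
  thresholds <- c(ceiling(0.6 * n_runs), ceiling(0.8 * n_runs), n_runs)
  names(thresholds) <- paste0(">=", thresholds)
  blocks <- unique(unlist(lapply(per_run_sets, names)))
  report <- list()
  for (blk in blocks) {
    feats <- unlist(lapply(per_run_sets, function(s) unique(s[[blk]])))
    freq <- if (length(feats)) table(feats) else table(character(0))
    counts <- vapply(thresholds, function(t) sum(freq >= t), integer(1))
    report[[blk]] <- list(counts = counts,
                          frequency = freq,
                          robust = names(freq)[freq == n_runs])
  }
  structure(list(per_omics = report, n_runs = n_runs, thresholds = thresholds),
            class = "consensus_report")
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("<consensus_report over %d runs>\n", x$n_runs))
  for (blk in names(x$per_omics)) {
    cat(sprintf("  %s: %s\n", blk,
                paste(sprintf("%s: %d", names(x$per_omics[[blk]]$counts),
                              x$per_omics[[blk]]$counts), collapse = ", ")))
  }
  invisible(x)
}

#' Cross-loss novelty of robust features
#'
#' Features robust under the focal loss that are not robust under any of
#' the comparison losses.
#'
#' @param focal a `consensus_report` for the loss of interest.
#' @param others list of `consensus_report`s for the comparison losses.
#' @return named list (per omics type) of novel feature ids.
#' @export
novelty <- function(focal, others) {
  stopifnot(inherits(focal, "consensus_report"))
  out <- list()
  for (blk in names(focal$per_omics)) {
    other_robust <- unlist(lapply(others, function(r) r$per_omics[[blk]]$robust))
    out[[blk]] <- setdiff(focal$per_omics[[blk]]$robust, other_robust)
  }
  out
}

#' Z-score matrix for heatmap rendering
#'
#' Per-feature z-scores of the selected features (on the pre-scaling
#' data), clipped to `[-3, 3]`, with samples ordered by cluster label.
#' Constant features yield all-zero rows.
#'
#' @param d a `multiomics_dataset` (pre-scaling values).
#' @param features character vector of qualified feature ids to include.
#' @param labels cluster labels used to order the columns.
#' @return list: `matrix` (features x samples, clipped z-scores),
#'   `sample_order`, `labels` (reordered).
#' @export
zscore_matrix <- function(d, features, labels) {
  stopifnot(inherits(d, "multiomics_dataset"))
  missing <- setdiff(features, d$feature_ids)
  if (length(missing)) stopf("unknown feature id(s): %s", paste(missing, collapse = ", "))
  sub <- d$matrix[, features, drop = FALSE]
  mu <- colMeans(sub)
  sdv <- apply(sub, 2, stats::sd)
  sdv[sdv < EPS_SCALE] <- 1
  z <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
  z <- pmin(pmax(z, -3), 3)
  ord <- order(labels)
  list(matrix = t(z[ord, , drop = FALSE]), sample_order = ord, labels = labels[ord])
}
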