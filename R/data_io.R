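## Containers and preprocessing for per-omics matrices and the stacked
## multi-omics model input.

OMICS_TYPES <- c("mrna", "mirna", "methylation")

#' Construct a per-omics data matrix
#'
#' A thin validated container for one omics layer: a samples x features
#' numeric matrix plus identifiers and the omics type. Values may contain
#' `NA` before imputation; they must be finite afterwards.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sample_ids character vector of sample identifiers (defaults to
#'   rownames of `values`).
#' @param feature_ids character vector of feature identifiers (defaults to
#'   colnames of `values`).
#' @param omics_type one of `"mrna"`, `"mirna"`, `"methylation"`.
#' @return an object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, sample_ids = rownames(values),
                         feature_ids = colnames(values),
                         omics_type = c("mrna", "mirna", "methylation")) {
  omics_type <- match.arg(omics_type)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) stopf("sample_ids required (no rownames on values)")
  if (is.null(feature_ids)) stopf("feature_ids required (no colnames on values)")
  if (nrow(values) != length(sample_ids)) stopf("row count != number of sample ids")
  if (ncol(values) != length(feature_ids)) stopf("column count != number of feature ids")
  if (anyDuplicated(feature_ids)) stopf("duplicate feature ids in %s matrix", omics_type)
  rownames(values) <- sample_ids
  colnames(values) <- feature_ids
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 feature_ids = as.character(feature_ids), omics_type = omics_type),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix %s: %d samples x %d features, %d NA>\n",
              x$omics_type, nrow(x$values), ncol(x$values), sum(is.na(x$values))))
  invisible(x)
}

#' Construct a clinical survival table
#'
#' @param sample_ids character sample identifiers.
#' @param time observed survival time in days, non-negative.
#' @param event event indicator: 1 = death observed, 0 = alive/censored.
#' @param covariates optional data.frame of extra clinical columns
#'   (e.g. grade, risk factor) aligned to `sample_ids`.
#' @return a `data.frame` with class `survival_table`, columns `sample_id`,
#'   `time`, `event` plus any covariates.
#' @export
survival_table <- function(sample_ids, time, event, covariates = NULL) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (length(sample_ids) != length(time) || length(time) != length(event)) {
    stopf("sample_ids, time and event must have equal length")
  }
  if (anyNA(time) || any(time < 0)) stopf("survival time must be non-negative and non-missing")
  if (!all(event %in% c(0L, 1L))) stopf("event indicator must be 0 (censored) or 1 (death)")
  df <- data.frame(sample_id = as.character(sample_ids), time = time, event = event,
                   stringsAsFactors = FALSE)
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(sample_ids))
    df <- cbind(df, covariates)
  }
  class(df) <- c("survival_table", "data.frame")
  df
}

#' Read an omics matrix from TSV/CSV
#'
#' Expects a header row of feature identifiers and sample identifiers in the
#' first column. Delimiter is inferred from the file extension (`.csv` =>
#' comma, otherwise tab); gzip-compressed files are read transparently.
#'
#' @param path file path.
#' @param omics_type one of `"mrna"`, `"mirna"`, `"methylation"`.
#' @return an [omics_matrix].
#' @export
read_omics_matrix <- function(path, omics_type) {
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  omics_matrix(values, ids, colnames(values), omics_type)
}

#' Write an omics matrix as TSV
#' @param m an [omics_matrix].
#' @param path output path (`.gz` suffix compresses).
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(sample_id = m$sample_ids, m$values, check.names = FALSE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical survival table from TSV
#'
#' Requires columns `sample_id`, `time`, `event`; any further columns are
#' kept as covariates.
#' @param path file path.
#' @return a [survival_table].
#' @export
read_survival_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stopf("clinical table must contain columns: %s", paste(need, collapse = ", "))
  }
  extra <- setdiff(names(df), need)
  survival_table(df$sample_id, df$time, df$event,
                 covariates = if (length(extra)) df[, extra, drop = FALSE] else NULL)
}

#' Write a clinical survival table as TSV
#' @param surv a [survival_table].
#' @param path output path.
#' @export
write_survival_table <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

bad_mask <- function(values) is.na(values) | values == 0

#' Remove features with too many missing or zero values
#'
#' A feature is dropped when its fraction of "bad" entries (missing, or
#' exactly zero) across samples exceeds `max_bad_fraction`; the boundary
#' fraction itself is retained. Applied before [filter_samples] — the order
#' matters and the pipeline always filters features first.
#'
#' @param m an [omics_matrix].
#' @param max_bad_fraction maximum tolerated bad fraction, in (0, 1).
#' @return the filtered [omics_matrix], column order preserved.
#' @export
filter_features <- function(m, max_bad_fraction = 0.20) {
  stopifnot(inherits(m, "omics_matrix"))
  if (max_bad_fraction <= 0 || max_bad_fraction >= 1) stopf("max_bad_fraction must be in (0,1)")
  frac <- colMeans(bad_mask(m$values))
  keep <- frac <= max_bad_fraction
  if (!any(keep)) stopf("all %s features removed by the missing/zero filter", m$omics_type)
  omics_matrix(m$values[, keep, drop = FALSE], m$sample_ids, m$feature_ids[keep], m$omics_type)
}

#' Remove samples with too many missing or zero features
#'
#' Applied after [filter_features], mirroring the preprocessing order of the
#' original pipeline. Removed sample ids are reported via `message`.
#'
#' @inheritParams filter_features
#' @return the filtered [omics_matrix], row order preserved.
#' @export
filter_samples <- function(m, max_bad_fraction = 0.20) {
  stopifnot(inherits(m, "omics_matrix"))
  if (max_bad_fraction <= 0 || max_bad_fraction >= 1) stopf("max_bad_fraction must be in (0,1)")
  frac <- rowMeans(bad_mask(m$values))
  keep <- frac <= max_bad_fraction
  if (!any(keep)) stopf("all %s samples removed by the missing/zero filter", m$omics_type)
  if (any(!keep)) {
    message(sprintf("filter_samples(%s): removed %d sample(s): %s", m$omics_type,
                    sum(!keep), paste(m$sample_ids[!keep], collapse = ", ")))
  }
  omics_matrix(m$values[keep, , drop = FALSE], m$sample_ids[keep], m$feature_ids, m$omics_type)
}

#' K-nearest-neighbour imputation of missing values
#'
#' Fills each missing entry with the mean, at that sample, of the `k`
#' features nearest to the incomplete feature. Distance between two features
#' is the root mean squared difference over their mutually observed samples
#' (so features with different missingness patterns remain comparable).
#' Non-missing entries are returned unchanged.
#'
#' @param m an [omics_matrix]; run the filters first so that no feature or
#'   sample is entirely missing.
#' @param k number of neighbouring features to average, default 10.
#' @return the imputed [omics_matrix] with no remaining `NA`.
#' @export
knn_impute <- function(m, k = 10) {
  stopifnot(inherits(m, "omics_matrix"), k >= 1)
  vals <- m$values
  if (!anyNA(vals)) return(m)
  if (any(colSums(!is.na(vals)) == 0)) stopf("a feature is entirely missing; filter first")
  if (any(rowSums(!is.na(vals)) == 0)) stopf("a sample is entirely missing; filter first")
  fmat <- t(vals)                       # features x samples
  incomplete <- which(rowSums(is.na(fmat)) > 0)
  out <- fmat
  for (f in incomplete) {
    diffs <- sweep(fmat, 2, fmat[f, ])  # feature rows minus target feature
    d2 <- rowMeans(diffs^2, na.rm = TRUE)
    d2[f] <- Inf
    miss <- which(is.na(fmat[f, ]))
    for (s in miss) {
      cand <- which(!is.na(fmat[, s]) & is.finite(d2))
      if (!length(cand)) stopf("no observed neighbour available to impute feature %s", m$feature_ids[f])
      kk <- min(k, length(cand))
      nn <- cand[order(d2[cand])[seq_len(kk)]]
      out[f, s] <- mean(fmat[nn, s])
    }
  }
  omics_matrix(t(out), m$sample_ids, m$feature_ids, m$omics_type)
}

#' Intersect samples across omics layers and stack into one matrix
#'
#' Restricts all three omics matrices and the clinical table to the samples
#' present in every source, then concatenates the feature columns in the
#' order mRNA, miRNA, methylation. Feature identifiers are qualified by
#' omics type (`"mrna:GENE"`). The survival rows are reordered to match the
#' matrix rows exactly.
#'
#' @param mrna,mirna,methyl [omics_matrix] objects of the matching types.
#' @param surv a [survival_table].
#' @return a `multiomics_dataset`: list with elements `matrix` (samples x
#'   total features), `blocks` (named list of column index vectors),
#'   `sample_ids`, `feature_ids`, `survival`.
#' @export
intersect_and_stack <- function(mrna, mirna, methyl, surv) {
  stopifnot(inherits(mrna, "omics_matrix"), inherits(mirna, "omics_matrix"),
            inherits(methyl, "omics_matrix"), inherits(surv, "survival_table"))
  layers <- list(mrna = mrna, mirna = mirna, methylation = methyl)
  common <- Reduce(intersect, c(lapply(layers, `[[`, "sample_ids"), list(surv$sample_id)))
  if (!length(common)) {
    stopf("no common samples (mrna: %d, mirna: %d, methylation: %d, clinical: %d)",
          length(mrna$sample_ids), length(mirna$sample_ids),
          length(methyl$sample_ids), nrow(surv))
  }
  common <- mrna$sample_ids[mrna$sample_ids %in% common]   # deterministic order
  mats <- lapply(layers, function(l) l$values[common, , drop = FALSE])
  widths <- vapply(mats, ncol, integer(1))
  ends <- cumsum(widths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  blocks <- Map(function(s, e) seq.int(s, e), starts, ends)
  names(blocks) <- names(layers)
  feature_ids <- unlist(Map(function(l, nm) paste0(nm, ":", l$feature_ids),
                            layers, names(layers)), use.names = FALSE)
  mat <- do.call(cbind, mats)
  colnames(mat) <- feature_ids
  si <- as.data.frame(surv)[match(common, surv$sample_id), , drop = FALSE]
  rownames(si) <- NULL
  surv2 <- survival_table(si$sample_id, si$time, si$event,
                          covariates = if (ncol(si) > 3) si[, -(1:3), drop = FALSE] else NULL)
  multiomics_dataset(mat, blocks, surv2)
}

#' Construct a stacked multi-omics dataset
#'
#' @param matrix numeric samples x features matrix with qualified feature
#'   column names and sample rownames.
#' @param blocks named list of column index vectors, one per omics type;
#'   must partition the columns exactly.
#' @param survival a [survival_table] aligned to the matrix rows.
#' @return a `multiomics_dataset`.
#' @export
multiomics_dataset <- function(matrix, blocks, survival) {
  stopifnot(is.matrix(matrix), inherits(survival, "survival_table"))
  idx <- sort(unlist(blocks, use.names = FALSE))
  if (!identical(idx, seq_len(ncol(matrix)))) stopf("blocks must partition the matrix columns exactly")
  if (nrow(matrix) != nrow(survival)) stopf("matrix rows and survival rows differ")
  if (!identical(rownames(matrix), survival$sample_id)) {
    if (is.null(rownames(matrix))) rownames(matrix) <- survival$sample_id
    else stopf("matrix row order does not match survival sample order")
  }
  structure(list(matrix = matrix, blocks = blocks,
                 sample_ids = rownames(matrix), feature_ids = colnames(matrix),
                 survival = survival),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  w <- vapply(x$blocks, length, integer(1))
  cat(sprintf("<multiomics_dataset: %d samples x %d features (%s), %d events>\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s %d", names(w), w), collapse = ", "),
              sum(x$survival$event)))
  invisible(x)
}

#' Scale each sample row to unit Euclidean norm
#'
#' The scaling used for the baseline architecture's input: each patient's
#' stacked feature vector is divided by its L2 norm. All-zero rows are left
#' as zeros (and reported).
#'
#' @param d a `multiomics_dataset` or plain numeric matrix.
#' @return the same type with rescaled values.
#' @export
scale_unit_norm <- function(d) {
  mat <- if (inherits(d, "multiomics_dataset")) d$matrix else d
  assert_finite_matrix(mat, "input")
  nrm <- sqrt(rowSums(mat^2))
  zero <- nrm == 0
  if (any(zero)) message(sprintf("scale_unit_norm: %d all-zero row(s) left unscaled", sum(zero)))
  nrm[zero] <- 1
  out <- mat / nrm
  if (inherits(d, "multiomics_dataset")) { d$matrix <- out; d } else out
}

#' Scale each feature column into [0, 1]
#'
#' The scaling used for the custom architecture's input: a per-feature
#' affine map of min to 0 and max to 1. Constant features map to 0.
#'
#' @param d a `multiomics_dataset` or plain numeric matrix.
#' @return the same type with rescaled values.
#' @export
scale_minmax <- function(d) {
  mat <- if (inherits(d, "multiomics_dataset")) d$matrix else d
  assert_finite_matrix(mat, "input")
  lo <- apply(mat, 2, min)
  hi <- apply(mat, 2, max)
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(sweep(mat, 2, lo), 2, rng, "/")
  out[, const] <- 0
  if (inherits(d, "multiomics_dataset")) { d$matrix <- out; d } else out
}

#' Full preprocessing pipeline for raw omics layers
#'
#' Applies, in order: feature filtering, sample filtering, KNN imputation on
#' each layer, then sample intersection and stacking. Model-specific scaling
#' (unit-norm or min-max) is applied later, per architecture.
#'
#' @param mrna,mirna,methyl raw [omics_matrix] layers.
#' @param surv a [survival_table].
#' @param feature_bad_fraction,sample_bad_fraction filter thresholds.
#' @param knn_k neighbours for imputation.
#' @return a `multiomics_dataset`.
#' @export
preprocess_omics <- function(mrna, mirna, methyl, surv,
                             feature_bad_fraction = 0.20,
                             sample_bad_fraction = 0.20,
                             knn_k = 10) {
  clean <- lapply(list(mrna, mirna, methyl), function(m) {
    m <- filter_features(m, feature_bad_fraction)
    m <- filter_samples(m, sample_bad_fraction)
    knn_impute(m, knn_k)
  })
  intersect_and_stack(clean[[1]], clean[[2]], clean[[3]], surv)
}
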