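## Orchestration: one seeded run of a loss regime end-to-end, and the
## multi-seed comparison over losses with consensus and novelty reporting.

#' Run configuration
#'
#' @param losses character vector of loss names to run.
#' @param seeds integer seeds, one pipeline run per seed (default 10 runs).
#' @param k_range candidate cluster counts for the k-means routes.
#' @param cox_alpha Cox-filter threshold for the baseline losses.
#' @param top_fraction,p_cut feature-selection thresholds; `p_cut` defaults
#'   to the Bonferroni correction 0.05 / number of runs.
#' @param epochs optional epoch override (testing at reduced depth).
#' @param out_dir optional directory; when set, per-run artefacts are
#'   written beneath it.
#' @return a `run_config` list.
#' @export
run_config <- function(losses = c("BCE", "MSE", "L_RC", "L_RS", "L_RSC"),
                       seeds = 1:10, k_range = 2:5, cox_alpha = 0.05,
                       top_fraction = 0.10, p_cut = NULL, epochs = NULL,
                       out_dir = NULL) {
  p_cut <- p_cut %||% (0.05 / length(seeds))
  structure(list(losses = losses, seeds = as.integer(seeds), k_range = k_range,
                 cox_alpha = cox_alpha, top_fraction = top_fraction,
                 p_cut = p_cut, epochs = epochs, out_dir = out_dir),
            class = "run_config")
}

loss_variant <- function(loss_name) {
  if (loss_name %in% c("BCE", "MSE")) "baseline" else "custom"
}

## Model-input scaling per variant. BCE needs inputs in [0, 1]: features
## are shifted to a zero minimum before the per-sample unit-norm scaling so
## that data with negative values (e.g. synthetic Gaussians) remains valid.
scale_for_model <- function(dataset, loss_name) {
  if (loss_variant(loss_name) == "custom") return(scale_minmax(dataset))
  if (loss_name == "BCE") {
    lo <- apply(dataset$matrix, 2, min)
    dataset$matrix <- sweep(dataset$matrix, 2, pmin(lo, 0))
  }
  scale_unit_norm(dataset)
}

#' Execute one seeded run of a loss regime
#'
#' Scales the preprocessed dataset as the architecture requires, builds and
#' trains the autoencoder, derives cluster labels by the route the loss
#' dictates (baselines: Cox-filter the bottleneck then k-means with
#' silhouette-selected k; `L_RS`: k-means over all bottleneck features;
#' `L_RC`/`L_RSC`: nearest final training centroid), scores the clustering
#' (silhouette, pairwise log-rank), and identifies the top differentiating
#' original features (two-step scaling + ANOVA + top-fraction/Bonferroni
#' selection).
#'
#' @param dataset a preprocessed `multiomics_dataset` (unscaled values).
#' @param loss_name one of `"BCE"`, `"MSE"`, `"L_RC"`, `"L_RS"`,
#'   `"L_RSC"`.
#' @param seed integer run seed (weight initialisation, dropout, k-means
#'   restarts).
#' @param config a [run_config].
#' @return a `run_result` list: `loss`, `seed`, `k`, `labels`,
#'   `silhouette`, `logrank_p` (headline: smallest pairwise),
#'   `logrank_matrix`, `cluster_sizes`, `bottleneck`, `cox_table` (baseline
#'   losses), `anova`, `top_features`, `trace`.
#' @export
run_one <- function(dataset, loss_name, seed, config = run_config()) {
  stopifnot(inherits(dataset, "multiomics_dataset"))
  variant <- loss_variant(loss_name)
  spec <- loss_spec(loss_name)
  arch <- architecture_spec(variant, epochs = config$epochs)
  scaled <- scale_for_model(dataset, loss_name)
  state <- build_autoencoder(arch, ncol(scaled$matrix), seed = seed,
                             survival_branch = spec$uses_survival)
  state <- train_autoencoder(state, scaled, spec)
  B <- encode(state, scaled$matrix)
  rownames(B) <- dataset$sample_ids

  cox_table <- NULL
  if (loss_name %in% c("BCE", "MSE")) {
    flt <- filter_bottleneck(B, dataset$survival, alpha = config$cox_alpha)
    cox_table <- flt$table
    cl <- select_k(B[, flt$indices, drop = FALSE], config$k_range, seed = seed)
  } else if (loss_name == "L_RS") {
    cl <- select_k(B, config$k_range, seed = seed)
  } else {
    cs <- centroid_state(state$centroids, state$assignments_data_order)
    cl <- labels_from_centroids(B, cs)
  }

  lr_mat <- pairwise_logrank(dataset$survival, cl$labels)
  lr_headline <- min(lr_mat, na.rm = TRUE)

  scaled_fd <- twostep_scale(dataset)
  anova_tab <- anova_per_feature(scaled_fd, cl$labels)
  tops <- top_features(anova_tab, config$top_fraction, config$p_cut)

  res <- structure(list(loss = loss_name, seed = as.integer(seed),
                        k = cl$k, labels = cl$labels,
                        silhouette = cl$silhouette,
                        logrank_p = lr_headline, logrank_matrix = lr_mat,
                        cluster_sizes = as.integer(tabulate(cl$labels, cl$k)),
                        bottleneck = B, cox_table = cox_table,
                        anova = anova_tab, top_features = tops,
                        trace = state$trace),
                   class = "run_result")
  if (!is.null(config$out_dir)) write_run_result(res, config$out_dir)
  res
}

#' Write the artefacts of one run
#'
#' Emits, under `<out_dir>/<loss>_seed<seed>/`: cluster labels
#' (sample_id, cluster TSV), the per-feature ANOVA table, top features per
#' omics type, the per-feature Cox table for baseline losses, the per-epoch
#' trace, and a machine-readable run summary JSON.
#'
#' @param res a `run_result`.
#' @param out_dir parent output directory.
#' @return the run directory, invisibly.
#' @export
write_run_result <- function(res, out_dir) {
  dir <- file.path(out_dir, sprintf("%s_seed%d", res$loss, res$seed))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(data.frame(sample_id = rownames(res$bottleneck),
                                cluster = res$labels),
                     file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(res$anova), file.path(dir, "anova.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$cox_table)) {
    utils::write.table(res$cox_table, file.path(dir, "cox_bottleneck.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$trace)) {
    utils::write.table(res$trace, file.path(dir, "trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(run_summary(res), file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Machine-readable summary of a run
#'
#' Deterministic content only (no timestamps): identical configuration and
#' seed yield byte-identical JSON.
#'
#' @param res a `run_result`.
#' @return a named list suitable for `jsonlite::write_json`.
#' @export
run_summary <- function(res) {
  list(loss = res$loss, seed = res$seed, k = res$k,
       silhouette = res$silhouette, logrank_p = res$logrank_p,
       cluster_sizes = res$cluster_sizes,
       n_top_features = lapply(res$top_features, length),
       top_features = res$top_features)
}

#' Run every configured loss over every seed and compare
#'
#' For each loss: runs the pipeline once per seed, selects the best run by
#' smallest headline log-rank P (ties to higher silhouette), aggregates the
#' per-run top features into a cross-run consensus, and finally computes
#' each loss's novel robust features against all other losses. Individual
#' run failures are caught and enumerated, leaving a partial report.
#'
#' @param dataset a preprocessed `multiomics_dataset`.
#' @param config a [run_config].
#' @return a `comparison_report`: per loss, min/max silhouette and
#'   log-rank P, best-run summary, consensus report, novel features; plus
#'   `failures`.
#' @export
run_all <- function(dataset, config = run_config()) {
  per_loss <- list()
  failures <- list()
  for (loss in config$losses) {
    runs <- list()
    for (seed in config$seeds) {
      r <- tryCatch(run_one(dataset, loss, seed, config),
                    error = function(e) e)
      if (inherits(r, "error")) {
        failures[[sprintf("%s_seed%d", loss, seed)]] <- conditionMessage(r)
      } else {
        runs[[length(runs) + 1L]] <- r
      }
    }
    if (!length(runs)) next
    ps <- vapply(runs, `[[`, numeric(1), "logrank_p")
    sils <- vapply(runs, `[[`, numeric(1), "silhouette")
    best <- order(ps, -sils)[1]
    cons <- consensus(lapply(runs, `[[`, "top_features"), n_runs = length(runs))
    per_loss[[loss]] <- list(
      loss = loss,
      logrank_p_range = c(lowest = min(ps), highest = max(ps)),
      silhouette_range = c(lowest = min(sils, na.rm = TRUE),
                           highest = max(sils, na.rm = TRUE)),
      best_run = run_summary(runs[[best]]),
      best_run_full = runs[[best]],
      consensus = cons)
  }
  for (loss in names(per_loss)) {
    others <- per_loss[names(per_loss) != loss]
    per_loss[[loss]]$novel <- novelty(per_loss[[loss]]$consensus,
                                      lapply(others, `[[`, "consensus"))
  }
  structure(list(per_loss = per_loss, failures = failures,
                 config = config[c("losses", "seeds", "k_range")]),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  for (loss in names(x$per_loss)) {
    pl <- x$per_loss[[loss]]
    cat(sprintf("  %-6s logrank P [%0.3g, %0.3g]  silhouette [%0.3f, %0.3f]  best k=%d sizes %s\n",
                loss, pl$logrank_p_range[1], pl$logrank_p_range[2],
                pl$silhouette_range[1], pl$silhouette_range[2],
                pl$best_run$k, paste(pl$best_run$cluster_sizes, collapse = "/")))
  }
  if (length(x$failures)) cat(sprintf("  %d failed run(s)\n", length(x$failures)))
  invisible(x)
}
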