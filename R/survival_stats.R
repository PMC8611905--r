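## Survival statistics downstream of the autoencoder: univariate Cox
## models for bottleneck-feature filtering, pairwise log-rank tests
## between clusters, Kaplan-Meier curves, and the median-split prognostic
## test for individual omics features. Model fitting is delegated to the
## survival package (coxph/survdiff/survfit) with Breslow tie handling,
## consistent with the Breslow form of the training loss.

#' Univariate Cox proportional-hazards fit
#'
#' Fits `Surv(time, event) ~ x` by partial-likelihood maximisation
#' (Breslow ties) and reports the coefficient, hazard ratio, and the score
#' (log-rank) test P-value. A zero-variance covariate or a fit that fails
#' to converge is returned flagged rather than as an error, since
#' near-separation covariates are expected downstream (bottleneck features
#' can be almost perfectly prognostic).
#'
#' @param x numeric covariate, one value per sample.
#' @param surv a [survival_table], or anything with `time`/`event` columns.
#' @return a `cox_fit` list: `beta`, `hazard_ratio`, `se` (standard error
#'   of `beta`), `p_value`, `converged`.
#' @export
cox_univariate <- function(x, surv) {
  time <- surv$time
  event <- surv$event
  if (sum(event) < 1) stopf("no events in the data; Cox model undefined")
  if (anyNA(x) || any(!is.finite(x))) stopf("covariate must be finite")
  if (stats::sd(x) == 0) {
    return(structure(list(beta = NA_real_, hazard_ratio = NA_real_,
                          se = NA_real_, p_value = NA_real_, converged = FALSE),
                     class = "cox_fit"))
  }
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(iter.max = 50)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik", conditionMessage(w))) {
        converged <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit)[1])
  sc <- summary(fit)$sctest
  structure(list(beta = beta, hazard_ratio = exp(beta),
                 se = sqrt(unname(stats::vcov(fit)[1, 1])),
                 p_value = unname(sc["pvalue"]), converged = converged),
            class = "cox_fit")
}

#' Filter bottleneck features by univariate Cox significance
#'
#' The baseline (BCE/MSE) route to clustering: each bottleneck column is
#' screened with a univariate Cox model and only columns whose score-test
#' P-value falls below `alpha` are carried into clustering.
#'
#' @param b bottleneck matrix (samples x features).
#' @param surv a [survival_table] aligned to the rows of `b`.
#' @param alpha significance threshold, default 0.05.
#' @return list with `indices` (retained column indices) and `table` (a
#'   per-feature data.frame: feature, beta, hazard_ratio, p_value,
#'   converged, retained).
#' @export
filter_bottleneck <- function(b, surv, alpha = 0.05) {
  b <- as.matrix(b)
  fits <- lapply(seq_len(ncol(b)), function(j) cox_univariate(b[, j], surv))
  tab <- data.frame(
    feature = colnames(b) %||% paste0("bn", seq_len(ncol(b))),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    hazard_ratio = vapply(fits, `[[`, numeric(1), "hazard_ratio"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  tab$retained <- !is.na(tab$p_value) & tab$p_value < alpha
  idx <- which(tab$retained)
  if (!length(idx)) {
    stopf("no bottleneck feature passed the Cox filter at alpha = %g; inspect the fit table", alpha)
  }
  list(indices = idx, table = tab)
}

#' Pairwise log-rank tests between clusters
#'
#' Two-sided log-rank chi-squared test for every pair of groups.
#'
#' @param surv a [survival_table].
#' @param labels group labels, at least two non-empty groups.
#' @return symmetric matrix of P-values with `NA` diagonal, dimnames the
#'   group levels.
#' @export
pairwise_logrank <- function(surv, labels) {
  labels <- as.integer(labels)
  groups <- sort(unique(labels))
  if (length(groups) < 2) stopf("pairwise log-rank needs at least 2 groups")
  P <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (a in seq_along(groups)) {
    for (b in seq_along(groups)) {
      if (b <= a) next
      sel <- labels %in% groups[c(a, b)]
      sd <- survival::survdiff(
        survival::Surv(surv$time[sel], surv$event[sel]) ~ labels[sel])
      p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
      P[a, b] <- P[b, a] <- p
    }
  }
  P
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate for a subset of samples.
#'
#' @param surv a [survival_table].
#' @param mask logical or integer subset of samples; default all.
#' @return a `km_curve` list: `time`, `surv_prob` (non-increasing from 1),
#'   `n_risk`, `n_event`.
#' @export
km_curve <- function(surv, mask = NULL) {
  if (is.null(mask)) mask <- rep(TRUE, nrow(surv))
  time <- surv$time[mask]
  event <- surv$event[mask]
  if (!length(time)) stopf("empty sample mask")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, surv_prob = fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event),
            class = "km_curve")
}

#' Median-split prognostic test for one feature
#'
#' Splits samples into low (value less than or equal to the median) and
#' high (above the median) groups and compares their survival with a
#' log-rank test. When every value falls on one side (e.g. a constant
#' feature), the result carries `p_value = NA`.
#'
#' @param values numeric per-sample feature values.
#' @param surv a [survival_table].
#' @return list: `labels` (factor "low"/"high"), `p_value`.
#' @export
median_split_test <- function(values, surv) {
  if (anyNA(values) || any(!is.finite(values))) stopf("values must be finite")
  med <- stats::median(values)
  grp <- factor(ifelse(values <= med, "low", "high"), levels = c("low", "high"))
  if (length(unique(grp)) < 2) {
    message("median_split_test: one side of the split is empty; P undefined")
    return(list(labels = grp, p_value = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ grp)
  list(labels = grp,
       p_value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
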