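## The four training objectives and their weighted combinations.
##
## Conventions that matter for the weight balance and are easy to get
## wrong:
##   * the reconstruction loss averages the per-sample squared Euclidean
##     norm over samples only — NOT over samples x features, so it is
##     larger than the usual element-wise MSE by a factor of the feature
##     count;
##   * the Cox partial-likelihood loss is NOT normalised by n; its scale
##     grows with the number of events;
##   * the clustering loss can be negative (it rewards distance from the
##     second-nearest centroid).

#' Loss specification
#'
#' Names one of the five training objectives and carries its mixing
#' weights. Defaults follow the tuned values: for the two-term losses
#' `alpha = 0.25`, `beta = 0.75`; for the three-term hybrid
#' `alpha = 0.25`, `beta = 0.50`, `gamma = 0.25`.
#'
#' @param name one of `"BCE"`, `"MSE"`, `"L_RC"`, `"L_RS"`, `"L_RSC"`.
#' @param alpha weight on the reconstruction term.
#' @param beta weight on the survival term (for `L_RC`, on the clustering
#'   term).
#' @param gamma weight on the clustering term (hybrid loss only).
#' @return a `loss_spec` list with fields `name`, `alpha`, `beta`, `gamma`
#'   and logical flags `uses_survival`, `uses_clustering`.
#' @export
loss_spec <- function(name = c("L_RSC", "L_RC", "L_RS", "BCE", "MSE"),
                      alpha = NULL, beta = NULL, gamma = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    BCE   = list(alpha = 1, beta = 0, gamma = 0),
    MSE   = list(alpha = 1, beta = 0, gamma = 0),
    L_RC  = list(alpha = 0.25, beta = 0.75, gamma = 0),
    L_RS  = list(alpha = 0.25, beta = 0.75, gamma = 0),
    L_RSC = list(alpha = 0.25, beta = 0.50, gamma = 0.25))
  alpha <- alpha %||% defaults$alpha
  beta <- beta %||% defaults$beta
  gamma <- gamma %||% defaults$gamma
  if (any(c(alpha, beta, gamma) < 0)) stopf("loss weights must be non-negative")
  structure(list(name = name, alpha = alpha, beta = beta, gamma = gamma,
                 uses_survival = name %in% c("L_RS", "L_RSC"),
                 uses_clustering = name %in% c("L_RC", "L_RSC")),
            class = "loss_spec")
}

#' Reconstruction loss: mean per-sample squared Euclidean error
#'
#' `(1/n) * sum_i ||x_i - xhat_i||^2`, the average over samples of the
#' squared Euclidean distance between each input row and its
#' reconstruction. Note this is the element-wise mean squared error times
#' the number of features.
#'
#' @param x input matrix (samples x features).
#' @param x_hat reconstruction, same shape.
#' @return a non-negative scalar.
#' @export
loss_reconstruction <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat))) stopf("x and x_hat must have identical shape")
  mean(rowSums((x - x_hat)^2))
}

#' Binary cross-entropy reconstruction loss
#'
#' Mean over all matrix elements of
#' `-(x * log(x_hat) + (1 - x) * log(1 - x_hat))`. Predictions are clipped
#' to `[eps, 1 - eps]` before the logarithms.
#'
#' @param x input matrix with values in `[0, 1]`.
#' @param x_hat reconstruction, same shape.
#' @param eps clipping bound, default `1e-7`.
#' @return a non-negative scalar.
#' @export
loss_bce <- function(x, x_hat, eps = 1e-7) {
  if (!identical(dim(x), dim(x_hat))) stopf("x and x_hat must have identical shape")
  if (any(x < 0) || any(x > 1)) stopf("loss_bce: x must lie in [0, 1]")
  p <- pmin(pmax(x_hat, eps), 1 - eps)
  -mean(x * log(p) + (1 - x) * log(1 - p))
}

#' Centroid state for the clustering loss
#'
#' @param centroids k x d numeric matrix of centroid coordinates in
#'   bottleneck space.
#' @param assignments integer vector of per-sample cluster indices in
#'   `1..k` (the training loop's current group memberships).
#' @return a `centroid_state` list.
#' @export
centroid_state <- function(centroids, assignments) {
  centroids <- as.matrix(centroids)
  if (nrow(centroids) < 2) stopf("at least 2 centroids required")
  assignments <- as.integer(assignments)
  if (any(assignments < 1 | assignments > nrow(centroids))) {
    stopf("assignments index a non-existent centroid")
  }
  structure(list(centroids = centroids, assignments = assignments),
            class = "centroid_state")
}

## squared Euclidean distance from each row of b to each centroid (n x k)
centroid_sqdist <- function(b, centroids) {
  cross <- b %*% t(centroids)
  sweep(sweep(-2 * cross, 2, rowSums(centroids^2), "+"), 1, rowSums(b^2), "+")
}

## per-row nearest and second-nearest centroid indices; ties break to the
## lower centroid index
nearest_two_centroids <- function(b, centroids) {
  d2 <- centroid_sqdist(b, centroids)
  mu <- max.col(-d2, ties.method = "first")
  d2[cbind(seq_len(nrow(b)), mu)] <- Inf
  lambda <- max.col(-d2, ties.method = "first")
  list(mu = mu, lambda = lambda)
}

#' Clustering loss: attraction to nearest, repulsion from second-nearest
#'
#' `(1/n) { sum_i ||b_i - mu_i||^2 - sum_i ||b_i - lambda_i||^2 }`, where
#' `mu_i` is the centroid nearest to bottleneck row `b_i` and `lambda_i`
#' the second-nearest. Negative values are expected once clusters are tight
#' and well separated.
#'
#' @param b bottleneck matrix (samples x bottleneck width).
#' @param cs a [centroid_state]; only the centroid coordinates enter the
#'   loss value (nearest/second-nearest roles are recomputed from `b`).
#' @return a scalar, possibly negative.
#' @export
loss_clustering <- function(b, cs) {
  stopifnot(inherits(cs, "centroid_state"))
  b <- as.matrix(b)
  nt <- nearest_two_centroids(b, cs$centroids)
  dmu <- rowSums((b - cs$centroids[nt$mu, , drop = FALSE])^2)
  dla <- rowSums((b - cs$centroids[nt$lambda, , drop = FALSE])^2)
  mean(dmu) - mean(dla)
}

#' Survival ordering and risk-set bookkeeping
#'
#' Sorts samples by descending observed time (the presentation order the
#' survival loss requires) and records the event indicator. Samples with
#' tied observed times share the same risk set (Breslow convention).
#'
#' @param time observed time per sample (days).
#' @param event 0/1 event indicator.
#' @return a `survival_order` list with `perm` (ordering permutation),
#'   `time`, `event` (both already permuted).
#' @export
survival_order <- function(time, event) {
  stopifnot(length(time) == length(event))
  perm <- order(time, decreasing = TRUE)
  structure(list(perm = perm, time = time[perm], event = as.integer(event[perm])),
            class = "survival_order")
}

## Shared internals for the Cox partial-likelihood loss and its gradient.
## `scores` must already be in the order of `so` (descending time). Works
## in log space with a running log-sum-exp so large scores cannot overflow.
cox_pl_parts <- function(scores, so) {
  n <- length(scores)
  stopifnot(n == length(so$time))
  logS <- numeric(n)   # log sum_{j in R(t_i)} exp(s_j), per sample
  M <- -Inf
  S <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && so$time[j + 1L] == so$time[i]) j <- j + 1L
    grp <- i:j
    m2 <- max(M, max(scores[grp]))
    S <- S * exp(M - m2) + sum(exp(scores[grp] - m2))
    M <- m2
    logS[grp] <- M + log(S)
    i <- j + 1L
  }
  logS
}

#' Cox partial-likelihood survival loss
#'
#' `- sum_i delta_i { s_i - log sum_{j in R(t_i)} exp(s_j) }` with Breslow
#' risk sets, where `s_i` is the scalar survival-branch output for sample
#' `i` and `R(t_i)` contains every sample whose observed time is at least
#' `t_i`. Computed with a running log-sum-exp along the descending-time
#' ordering; no normalisation by `n` is applied.
#'
#' @param scores numeric vector of per-sample risk scores, aligned to the
#'   permuted order in `order`.
#' @param order a [survival_order].
#' @return a scalar; 0 when no events are present.
#' @export
loss_survival <- function(scores, order) {
  stopifnot(inherits(order, "survival_order"))
  if (!length(scores)) stopf("at least one sample required")
  logS <- cox_pl_parts(scores, order)
  -sum(order$event * (scores - logS))
}

## Gradient of loss_survival w.r.t. the (ordered) scores.
## d/ds_j = -delta_j + exp(s_j) * sum_{events i with t_i <= t_j} 1/S_i
loss_survival_grad <- function(scores, so) {
  n <- length(scores)
  logS <- cox_pl_parts(scores, so)
  ev <- which(so$event == 1L)
  g <- -as.numeric(so$event)
  if (length(ev)) {
    ## events are at positions in descending-time order; an event i has
    ## t_i <= t_j exactly when i's position >= j's tie-group start. Build
    ## suffix sums of exp(-logS_i) over event positions, honouring ties.
    contrib <- numeric(n)
    contrib[ev] <- exp(-logS[ev])
    suffix <- rev(cumsum(rev(contrib)))
    ## samples in the same tie group share the same risk sets; events in a
    ## tie group have t_i == t_j, which satisfies t_i <= t_j for the whole
    ## group, so the suffix must start at each group's first index.
    grp_start <- integer(n)
    i <- 1L
    while (i <= n) {
      j <- i
      while (j < n && so$time[j + 1L] == so$time[i]) j <- j + 1L
      grp_start[i:j] <- i
      i <- j + 1L
    }
    g <- g + exp(scores) * suffix[grp_start]
  }
  g
}

#' Combine loss terms under a loss specification
#'
#' @param spec a [loss_spec].
#' @param lr reconstruction term (squared-error or BCE, per `spec$name`).
#' @param ls survival term, required when `spec` uses survival.
#' @param lc clustering term, required when `spec` uses clustering.
#' @return the weighted scalar objective.
#' @export
combine_losses <- function(spec, lr, ls = NULL, lc = NULL) {
  stopifnot(inherits(spec, "loss_spec"))
  if (is.null(lr) || is.na(lr)) stopf("reconstruction term missing")
  switch(spec$name,
    BCE = lr,
    MSE = lr,
    L_RC = {
      if (is.null(lc) || is.na(lc)) stopf("clustering term missing for L_RC")
      spec$alpha * lr + spec$beta * lc
    },
    L_RS = {
      if (is.null(ls) || is.na(ls)) stopf("survival term missing for L_RS")
      spec$alpha * lr + spec$beta * ls
    },
    L_RSC = {
      if (is.null(ls) || is.na(ls)) stopf("survival term missing for L_RSC")
      if (is.null(lc) || is.na(lc)) stopf("clustering term missing for L_RSC")
      spec$alpha * lr + spec$beta * ls + spec$gamma * lc
    })
}
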