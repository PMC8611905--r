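## Clustering of bottleneck representations: k-means with kmeans++
## seeding, silhouette scoring, k selection, and nearest-centroid
## labelling from a trained state.

#' Cluster result container
#'
#' @param labels integer cluster labels in `1..k`.
#' @param k number of clusters.
#' @param silhouette mean silhouette score of the labelling (or `NA`).
#' @param source `"kmeans_on_bottleneck"` or `"final_training_centroids"`.
#' @param sse total within-cluster sum of squares (when available).
#' @return a `cluster_result` list.
#' @export
cluster_result <- function(labels, k, silhouette, source, sse = NA_real_) {
  structure(list(labels = as.integer(labels), k = as.integer(k),
                 silhouette = silhouette, source = source, sse = sse),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result: k=%d (%s), silhouette %.3f, sizes %s>\n",
              x$k, x$source, x$silhouette,
              paste(tabulate(x$labels, x$k), collapse = "/")))
  invisible(x)
}

## kmeans++ seeding: first centre uniform, subsequent centres drawn with
## probability proportional to squared distance to the nearest chosen
## centre.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ])^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1)
    } else {
      centers[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ])^2))
  }
  X[centers, , drop = FALSE]
}

#' K-means clustering with kmeans++ initialisation
#'
#' Lloyd's algorithm (via `stats::kmeans`) started from kmeans++ seeds,
#' with `nstart` independent restarts; the restart with the lowest total
#' within-cluster sum of squares wins. Deterministic given `seed`.
#'
#' @param b numeric matrix (samples x features), typically a bottleneck.
#' @param k number of clusters, `2 <= k <= n`.
#' @param seed integer seed controlling seeding draws.
#' @param nstart number of kmeans++ restarts, default 10.
#' @param iter.max Lloyd iteration cap.
#' @return a [cluster_result].
#' @export
kmeans_pp <- function(b, k, seed = 1L, nstart = 10, iter.max = 100) {
  b <- as.matrix(b)
  n <- nrow(b)
  if (k > n) stopf("k = %d exceeds sample count %d", k, n)
  if (k < 2) stopf("k must be >= 2")
  if (k == n) {
    return(cluster_result(seq_len(n), n, 0, "kmeans_on_bottleneck", sse = 0))
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- with_seed(derive_seed(seed, 7000L + r), {
      centers <- kmeanspp_centers(b, k)
      centers <- centers + 1e-12 * (seq_len(k) - 1)   # guard duplicate seeds
      suppressWarnings(stats::kmeans(b, centers = centers,
                                     iter.max = iter.max, algorithm = "Lloyd"))
    })
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  sil <- silhouette_score(b, best$cluster)
  cluster_result(best$cluster, k, sil, "kmeans_on_bottleneck", sse = best$tot.withinss)
}

#' Mean silhouette score of a labelling
#'
#' For sample `i` with cohesion `a(i)` (mean Euclidean distance to the
#' other members of its own cluster) and separation `b(i)` (smallest mean
#' distance to the members of any other cluster),
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`. Members of singleton clusters
#' contribute `s(i) = 0`. Returns the mean over samples, in `[-1, 1]`.
#'
#' @param b numeric matrix (samples x features).
#' @param labels integer cluster labels; at least two distinct values.
#' @return scalar mean silhouette.
#' @export
silhouette_score <- function(b, labels) {
  b <- as.matrix(b)
  labels <- as.integer(labels)
  uq <- sort(unique(labels))
  if (length(uq) < 2) stopf("silhouette needs at least 2 clusters")
  D <- as.matrix(stats::dist(b))
  n <- nrow(b)
  ## mean distance from every sample to every cluster, via indicator algebra
  G <- outer(labels, uq, "==") * 1        # n x k membership
  sizes <- colSums(G)
  sums <- D %*% G                          # n x k: total distance to each cluster
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(labels[i], uq)
    if (sizes[ci] == 1) { s[i] <- 0; next }
    a <- sums[i, ci] / (sizes[ci] - 1)
    bmin <- min(sums[i, -ci] / sizes[-ci])
    m <- max(a, bmin)
    s[i] <- if (m == 0) 0 else (bmin - a) / m
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs [kmeans_pp] for every `k` in `k_range` and returns the result with
#' the highest silhouette; ties go to the smallest `k`.
#'
#' @param b numeric matrix.
#' @param k_range candidate cluster counts, default `2:5`.
#' @param seed integer seed (shared across the candidate fits).
#' @return the winning [cluster_result].
#' @export
select_k <- function(b, k_range = 2:5, seed = 1L) {
  fits <- lapply(k_range, function(k) kmeans_pp(b, k, seed = seed))
  sils <- vapply(fits, `[[`, numeric(1), "silhouette")
  fits[[which.max(sils)]]   # which.max takes the first (smallest k) on ties
}

#' Labels from a trained state's final centroids
#'
#' Nearest-centroid assignment of every bottleneck row (ties to the lower
#' centroid index), as used to read cluster membership off a network
#' trained with a clustering-aware loss.
#'
#' @param b bottleneck matrix.
#' @param cs a [centroid_state] (e.g. built from `state$centroids` and
#'   `state$assignments` after [train_autoencoder]).
#' @return a [cluster_result] with source `"final_training_centroids"`;
#'   silhouette is `NA` (with a warning) if only one cluster is occupied.
#' @export
labels_from_centroids <- function(b, cs) {
  stopifnot(inherits(cs, "centroid_state"))
  b <- as.matrix(b)
  d2 <- centroid_sqdist(b, cs$centroids)
  labels <- max.col(-d2, ties.method = "first")
  k <- nrow(cs$centroids)
  if (length(unique(labels)) < 2) {
    warning("only one centroid is occupied; silhouette undefined")
    sil <- NA_real_
  } else {
    sil <- silhouette_score(b, labels)
  }
  cluster_result(labels, k, sil, "final_training_centroids")
}
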