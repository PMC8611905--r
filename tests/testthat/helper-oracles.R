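# Independent naive reference implementations used as oracles, plus a
# session-level cache so expensive trained fixtures are shared across
# test files.

# -- naive loss oracles (double loops, no shared code with the package) --

naive_reconstruction <- function(x, x_hat) {
  tot <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) tot <- tot + (x[i, j] - x_hat[i, j])^2
  }
  tot / nrow(x)
}

naive_bce <- function(x, x_hat, eps = 1e-7) {
  tot <- 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      p <- min(max(x_hat[i, j], eps), 1 - eps)
      tot <- tot - (x[i, j] * log(p) + (1 - x[i, j]) * log(1 - p))
    }
  }
  tot / length(x)
}

naive_clustering <- function(b, centroids) {
  tot <- 0
  for (i in seq_len(nrow(b))) {
    d2 <- apply(centroids, 1, function(cen) sum((b[i, ] - cen)^2))
    ord <- order(d2)
    tot <- tot + d2[ord[1]] - d2[ord[2]]
  }
  tot / nrow(b)
}

naive_survival <- function(scores, time, event) {
  tot <- 0
  for (i in seq_along(scores)) {
    if (event[i] == 1) {
      risk <- which(time >= time[i])
      tot <- tot - (scores[i] - log(sum(exp(scores[risk]))))
    }
  }
  tot
}

# O(n^2) silhouette reference with the singleton-contributes-zero rule
naive_silhouette <- function(b, labels) {
  b <- as.matrix(b)
  n <- nrow(b)
  ed <- function(i, j) sqrt(sum((b[i, ] - b[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) ed(i, j), numeric(1)))
    bvals <- vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(vapply(which(labels == cl), function(j) ed(i, j), numeric(1)))
    }, numeric(1))
    bi <- min(bvals)
    s[i] <- (bi - a) / max(a, bi)
  }
  mean(s)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# -- cached fixtures shared across the suite --

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

get_fixture <- function() cached("fixture", easy_fixture())

# one full-depth trained run per loss, shared by module and acceptance tests
get_run <- function(loss, seed = 1) {
  cached(paste0("run_", loss, "_", seed),
         run_one(get_fixture()$dataset, loss, seed = seed,
                 run_config(seeds = 1)))
}
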