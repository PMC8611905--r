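## Autoencoder architectures and the bespoke training loop: warm-up epoch,
## furthest-pair centroid seeding, descending-survival sample ordering,
## per-epoch centroid refresh. The network is a four-dense-layer
## symmetric autoencoder (encoder: input -> h -> bottleneck; decoder:
## bottleneck -> h -> input) with an optional linear survival branch of
## width 1 on the bottleneck. Gradients are computed by hand-written
## backpropagation; there is no external deep-learning dependency.

#' Architecture specification
#'
#' Two fixed variants are provided. `baseline`: hidden widths 500-100-500,
#' tanh activations, dropout 0.5 on the non-bottleneck hidden layers, L1
#' kernel penalty 0.001, L2 activity penalty 0.0001 on the output layer,
#' per-sample stochastic gradient descent for 10 epochs; its input is
#' unit-norm scaled. `custom`: hidden widths 1000-100-1000, sigmoid
#' activations, L1 kernel penalty 0.001, full-batch Adam for 40 epochs
#' (one gradient step per epoch); its input is min-max scaled, and it is
#' the variant that hosts the survival branch and centroid machinery.
#'
#' @param variant `"baseline"` or `"custom"`.
#' @param epochs,batch_size,learning_rate,dropout,l1_kernel,l2_activity
#'   optional overrides of the variant defaults. `batch_size = Inf` means
#'   full batch.
#' @return an `architecture_spec` list.
#' @export
architecture_spec <- function(variant = c("custom", "baseline"),
                              epochs = NULL, batch_size = NULL,
                              learning_rate = NULL, dropout = NULL,
                              l1_kernel = NULL, l2_activity = NULL) {
  variant <- match.arg(variant)
  base <- switch(variant,
    baseline = list(hidden_dims = c(500L, 100L, 500L), activation = "tanh",
                    dropout = 0.5, l1_kernel = 1e-3, l2_activity = 1e-4,
                    optimizer = "sgd", learning_rate = 0.01,
                    batch_size = 1, epochs = 10L),
    custom   = list(hidden_dims = c(1000L, 100L, 1000L), activation = "sigmoid",
                    dropout = 0, l1_kernel = 1e-3, l2_activity = 0,
                    optimizer = "adam", learning_rate = 1e-3,
                    batch_size = Inf, epochs = 40L))
  base$epochs <- as.integer(epochs %||% base$epochs)
  base$batch_size <- batch_size %||% base$batch_size
  base$learning_rate <- learning_rate %||% base$learning_rate
  base$dropout <- dropout %||% base$dropout
  base$l1_kernel <- l1_kernel %||% base$l1_kernel
  base$l2_activity <- l2_activity %||% base$l2_activity
  base$variant <- variant
  base$bottleneck <- base$hidden_dims[2]
  structure(base, class = "architecture_spec")
}

act_fun <- function(name) {
  switch(name,
    tanh = list(f = tanh, dfd = function(h) 1 - h^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)), dfd = function(h) h * (1 - h)))
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Build an autoencoder training state
#'
#' Initialises all dense kernels with Glorot-uniform draws from `seed` and
#' biases at zero. The survival branch (a bias-free linear map from the
#' bottleneck to one scalar) is attached only when requested, i.e. for the
#' survival-aware losses.
#'
#' @param arch an [architecture_spec].
#' @param n_features input width (total stacked features).
#' @param seed integer seed for reproducible initialisation.
#' @param survival_branch attach the width-1 linear risk-score branch?
#' @return a `training_state` list holding parameters, optimiser slots,
#'   centroid state (once seeded) and the per-epoch trace.
#' @export
build_autoencoder <- function(arch, n_features, seed = 1L, survival_branch = FALSE) {
  stopifnot(inherits(arch, "architecture_spec"))
  if (n_features < arch$bottleneck) stopf("need at least %d input features", arch$bottleneck)
  dims <- c(n_features, arch$hidden_dims, n_features)
  params <- with_seed(derive_seed(seed, 1L), {
    W <- vector("list", 4)
    b <- vector("list", 4)
    for (l in 1:4) {
      W[[l]] <- glorot(dims[l], dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    Ws <- if (survival_branch) glorot(arch$bottleneck, 1L) else NULL
    list(W = W, b = b, Ws = Ws)
  })
  structure(list(arch = arch, n_features = n_features, seed = as.integer(seed),
                 W = params$W, b = params$b, Ws = params$Ws,
                 opt = NULL, centroids = NULL, assignments = NULL,
                 epoch = 0L, trace = NULL, rng_stream = 0L),
            class = "training_state")
}

#' @export
print.training_state <- function(x, ...) {
  cat(sprintf("<training_state: %s variant, %d features, epoch %d%s%s>\n",
              x$arch$variant, x$n_features, x$epoch,
              if (!is.null(x$Ws)) ", survival branch" else "",
              if (!is.null(x$centroids)) sprintf(", %d centroids", nrow(x$centroids)) else ""))
  invisible(x)
}

## Forward pass. `masks` is NULL (inference: no dropout) or a list of two
## dropout masks matching h1 and h3.
ae_forward <- function(state, X, masks = NULL) {
  a <- act_fun(state$arch$activation)
  z1 <- sweep(X %*% state$W[[1]], 2, state$b[[1]], "+")
  h1 <- a$f(z1)
  if (!is.null(masks)) h1 <- h1 * masks[[1]]
  z2 <- sweep(h1 %*% state$W[[2]], 2, state$b[[2]], "+")
  B <- a$f(z2)
  z3 <- sweep(B %*% state$W[[3]], 2, state$b[[3]], "+")
  h3 <- a$f(z3)
  if (!is.null(masks)) h3 <- h3 * masks[[2]]
  z4 <- sweep(h3 %*% state$W[[4]], 2, state$b[[4]], "+")
  Xhat <- a$f(z4)
  scores <- if (!is.null(state$Ws)) drop(B %*% state$Ws) else NULL
  list(h1 = h1, B = B, h3 = h3, Xhat = Xhat, scores = scores)
}

## Backward pass: given upstream gradients dXhat (n x p), dB_extra (n x d,
## from clustering loss), dscores (n, from survival loss), return gradient
## list matching the parameter layout. L1 kernel subgradients are added
## here.
ae_backward <- function(state, X, fwd, dXhat, dB_extra = NULL, dscores = NULL,
                        masks = NULL) {
  a <- act_fun(state$arch$activation)
  l1 <- state$arch$l1_kernel
  d4 <- dXhat * a$dfd(fwd$Xhat)
  gW4 <- crossprod(fwd$h3, d4) + l1 * sign(state$W[[4]])
  gb4 <- colSums(d4)
  dh3 <- d4 %*% t(state$W[[4]])
  if (!is.null(masks)) dh3 <- dh3 * masks[[2]]
  d3 <- dh3 * a$dfd(fwd$h3)
  gW3 <- crossprod(fwd$B, d3) + l1 * sign(state$W[[3]])
  gb3 <- colSums(d3)
  dB <- d3 %*% t(state$W[[3]])
  gWs <- NULL
  if (!is.null(dscores)) {
    dB <- dB + outer(dscores, drop(state$Ws))
    gWs <- crossprod(fwd$B, matrix(dscores, ncol = 1)) + l1 * sign(state$Ws)
  } else if (!is.null(state$Ws)) {
    gWs <- l1 * sign(state$Ws)
  }
  if (!is.null(dB_extra)) dB <- dB + dB_extra
  d2 <- dB * a$dfd(fwd$B)
  gW2 <- crossprod(fwd$h1, d2) + l1 * sign(state$W[[2]])
  gb2 <- colSums(d2)
  dh1 <- d2 %*% t(state$W[[2]])
  if (!is.null(masks)) dh1 <- dh1 * masks[[1]]
  d1 <- dh1 * a$dfd(fwd$h1)
  gW1 <- crossprod(X, d1) + l1 * sign(state$W[[1]])
  gb1 <- colSums(d1)
  list(W = list(gW1, gW2, gW3, gW4), b = list(gb1, gb2, gb3, gb4), Ws = gWs)
}

## Optimiser step over the flat parameter list; mutates and returns state.
opt_step <- function(state, grads) {
  lr <- state$arch$learning_rate
  if (state$arch$optimizer == "sgd") {
    for (l in 1:4) {
      state$W[[l]] <- state$W[[l]] - lr * grads$W[[l]]
      state$b[[l]] <- state$b[[l]] - lr * grads$b[[l]]
    }
    if (!is.null(grads$Ws)) state$Ws <- state$Ws - lr * grads$Ws
    return(state)
  }
  ## Adam with standard defaults (beta1 0.9, beta2 0.999, eps 1e-8)
  if (is.null(state$opt)) {
    zeros <- function(x) x * 0
    state$opt <- list(t = 0,
                      mW = lapply(state$W, zeros), vW = lapply(state$W, zeros),
                      mb = lapply(state$b, zeros), vb = lapply(state$b, zeros),
                      mWs = if (!is.null(state$Ws)) state$Ws * 0 else NULL,
                      vWs = if (!is.null(state$Ws)) state$Ws * 0 else NULL)
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$opt$t <- state$opt$t + 1
  t <- state$opt$t
  upd <- function(m, v, g) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    list(m = m, v = v, step = lr * mhat / (sqrt(vhat) + eps))
  }
  for (l in 1:4) {
    u <- upd(state$opt$mW[[l]], state$opt$vW[[l]], grads$W[[l]])
    state$opt$mW[[l]] <- u$m; state$opt$vW[[l]] <- u$v
    state$W[[l]] <- state$W[[l]] - u$step
    u <- upd(state$opt$mb[[l]], state$opt$vb[[l]], grads$b[[l]])
    state$opt$mb[[l]] <- u$m; state$opt$vb[[l]] <- u$v
    state$b[[l]] <- state$b[[l]] - u$step
  }
  if (!is.null(grads$Ws)) {
    u <- upd(state$opt$mWs, state$opt$vWs, grads$Ws)
    state$opt$mWs <- u$m; state$opt$vWs <- u$v
    state$Ws <- state$Ws - u$step
  }
  state
}

## Gradient of the active loss terms on one batch (rows Xb of the ordered
## matrix). `so` is the survival_order restricted to the batch (full batch
## when survival is active). Returns list(grads, terms).
batch_gradients <- function(state, Xb, spec, so = NULL, masks = NULL) {
  nb <- nrow(Xb)
  fwd <- ae_forward(state, Xb, masks = masks)
  arch <- state$arch
  if (spec$name == "BCE") {
    eps <- 1e-7
    p <- pmin(pmax(fwd$Xhat, eps), 1 - eps)
    lr_term <- -mean(Xb * log(p) + (1 - Xb) * log(1 - p))
    dXhat <- (p - Xb) / (p * (1 - p)) / length(Xb)
    dXhat[fwd$Xhat < eps | fwd$Xhat > 1 - eps] <- 0   # clipped region: flat
  } else {
    lr_term <- mean(rowSums((Xb - fwd$Xhat)^2))
    dXhat <- 2 * (fwd$Xhat - Xb) / nb
    dXhat <- dXhat * if (spec$name %in% c("MSE", "BCE")) 1 else spec$alpha
  }
  if (arch$l2_activity > 0) {
    lr_term <- lr_term + arch$l2_activity * sum(fwd$Xhat^2) / nb
    dXhat <- dXhat + 2 * arch$l2_activity * fwd$Xhat / nb
  }
  ls_term <- NA_real_
  dscores <- NULL
  if (spec$uses_survival) {
    ls_term <- loss_survival(fwd$scores, so)
    dscores <- spec$beta * loss_survival_grad(fwd$scores, so)
  }
  lc_term <- NA_real_
  dB_extra <- NULL
  if (spec$uses_clustering) {
    cs <- centroid_state(state$centroids, state$assignments)
    lc_term <- loss_clustering(fwd$B, cs)
    nt <- nearest_two_centroids(fwd$B, state$centroids)
    wC <- if (spec$name == "L_RC") spec$beta else spec$gamma
    dB_extra <- wC * (2 / nb) *
      (state$centroids[nt$lambda, , drop = FALSE] - state$centroids[nt$mu, , drop = FALSE])
  }
  grads <- ae_backward(state, Xb, fwd, dXhat, dB_extra = dB_extra,
                       dscores = dscores, masks = masks)
  list(grads = grads, lr = lr_term, ls = ls_term, lc = lc_term)
}

## Draw inverted-dropout masks for the two non-bottleneck hidden layers.
dropout_masks <- function(state, nb) {
  p <- state$arch$dropout
  if (p <= 0) return(NULL)
  h <- state$arch$hidden_dims
  m1 <- matrix(stats::rbinom(nb * h[1], 1, 1 - p), nb, h[1]) / (1 - p)
  m3 <- matrix(stats::rbinom(nb * h[3], 1, 1 - p), nb, h[3]) / (1 - p)
  list(m1, m3)
}

#' Encode samples to bottleneck space
#'
#' Inference-mode forward pass (dropout disabled); rows follow the input
#' sample order.
#'
#' @param state a trained (or freshly built) `training_state`.
#' @param X samples x features matrix, scaled as the architecture expects.
#' @return an n x bottleneck-width matrix.
#' @export
encode <- function(state, X) {
  if (inherits(X, "multiomics_dataset")) X <- X$matrix
  ae_forward(state, X)$B
}

#' Survival-branch risk scores
#'
#' @inheritParams encode
#' @return numeric vector of `W' phi(x_i)` scores.
#' @export
risk_scores <- function(state, X) {
  if (is.null(state$Ws)) stopf("state has no survival branch")
  if (inherits(X, "multiomics_dataset")) X <- X$matrix
  drop(encode(state, X) %*% state$Ws)
}

#' Warm-up epoch and furthest-pair centroid seeding
#'
#' Trains the network for one epoch with the reconstruction loss only,
#' passes the full data through the encoder in inference mode, picks the
#' two bottleneck rows at maximal pairwise Euclidean distance as seed
#' centroids (ties resolved to the lexicographically smallest index pair),
#' and assigns every sample to the nearer seed (ties to the lower index).
#' The warmed-up parameters are kept for subsequent combined-loss training.
#'
#' @param state a `training_state` built for the custom variant.
#' @param X scaled input matrix.
#' @return the updated `training_state` with `centroids` and `assignments`
#'   populated.
#' @export
warmup_and_seed_centroids <- function(state, X) {
  if (inherits(X, "multiomics_dataset")) X <- X$matrix
  if (nrow(X) < 2) stopf("need at least 2 samples to seed centroids")
  state <- run_epochs(state, X, loss_spec("MSE"), epochs = 1L, record = FALSE)
  state$epoch <- 0L   # trace epochs count combined-loss training only
  B <- encode(state, X)
  fp <- farthest_pair(B)
  state$centroids <- B[c(fp[1], fp[2]), , drop = FALSE]
  d2 <- centroid_sqdist(B, state$centroids)
  state$assignments <- max.col(-d2, ties.method = "first")
  state
}

## O(n^2) max-distance pair; ties to the lexicographically smallest (i, j).
farthest_pair <- function(B) {
  D <- as.matrix(stats::dist(B))
  best <- c(1L, 2L)
  bestd <- -Inf
  n <- nrow(D)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] > bestd + 1e-15) {
        bestd <- D[i, j]
        best <- c(i, j)
      }
    }
  }
  best
}

## Core epoch loop shared by warm-up and full training. Mutates/returns
## state; records the trace when `record`.
run_epochs <- function(state, X, spec, epochs, so = NULL, record = TRUE) {
  arch <- state$arch
  n <- nrow(X)
  bs <- if (is.infinite(arch$batch_size)) n else as.integer(arch$batch_size)
  starts <- seq(1L, n, by = bs)
  for (ep in seq_len(epochs)) {
    for (s in starts) {
      idx <- s:min(s + bs - 1L, n)
      masks <- NULL
      if (arch$dropout > 0) {
        state$rng_stream <- state$rng_stream + 1L
        masks <- with_seed(derive_seed(state$seed, 1000L + state$rng_stream),
                           dropout_masks(state, length(idx)))
      }
      bg <- batch_gradients(state, X[idx, , drop = FALSE], spec,
                            so = if (spec$uses_survival) so else NULL,
                            masks = masks)
      state <- opt_step(state, bg$grads)
    }
    state$epoch <- state$epoch + 1L
    if (spec$uses_clustering) state <- refresh_centroids(state, X)
    if (record) state <- record_epoch(state, X, spec, so)
  }
  state
}

## Per-epoch centroid update: mean bottleneck vector per assigned group,
## then nearest-centroid reassignment. An emptied group is re-seeded with
## the sample farthest from the mean of the remaining centroids.
refresh_centroids <- function(state, X) {
  B <- encode(state, X)
  k <- nrow(state$centroids)
  for (g in seq_len(k)) {
    rows <- state$assignments == g
    if (any(rows)) {
      state$centroids[g, ] <- colMeans(B[rows, , drop = FALSE])
    }
  }
  d2 <- centroid_sqdist(B, state$centroids)
  state$assignments <- max.col(-d2, ties.method = "first")
  ## repair any group emptied by the reassignment
  for (g in seq_len(k)) {
    if (!any(state$assignments == g)) {
      others <- state$centroids[-g, , drop = FALSE]
      ref <- colMeans(others)
      far <- which.max(rowSums(sweep(B, 2, ref)^2))
      state$centroids[g, ] <- B[far, ]
      d2 <- centroid_sqdist(B, state$centroids)
      state$assignments <- max.col(-d2, ties.method = "first")
      message(sprintf("epoch %d: empty cluster %d re-seeded", state$epoch, g))
    }
  }
  state
}

record_epoch <- function(state, X, spec, so) {
  fwd <- ae_forward(state, X)
  lr <- if (spec$name == "BCE") loss_bce(X, fwd$Xhat) else loss_reconstruction(X, fwd$Xhat)
  ls <- if (spec$uses_survival) loss_survival(fwd$scores, so) else NA_real_
  lc <- NA_real_
  sil <- NA_real_
  if (spec$uses_clustering) {
    cs <- centroid_state(state$centroids, state$assignments)
    lc <- loss_clustering(fwd$B, cs)
    if (length(unique(state$assignments)) >= 2) {
      sil <- silhouette_score(fwd$B, state$assignments)
    }
  }
  total <- combine_losses(spec, lr,
                          ls = if (spec$uses_survival) ls else NULL,
                          lc = if (spec$uses_clustering) lc else NULL)
  row <- data.frame(epoch = state$epoch, loss = total, recon = lr,
                    survival = ls, clustering = lc, silhouette = sil)
  state$trace <- rbind(state$trace, row)
  state
}

#' Train an autoencoder under one of the five objectives
#'
#' Implements the full training procedure. When the survival loss is
#' active, samples are sorted once into descending observed-time order and
#' never shuffled; when the clustering loss is active, a one-epoch
#' reconstruction-only warm-up is run, seed centroids are chosen as the
#' furthest bottleneck pair, and after every epoch centroids are recomputed
#' as per-group bottleneck means followed by nearest-centroid
#' reassignment. Baseline losses (BCE/MSE) train with per-sample SGD and
#' dropout; the custom variant takes exactly one full-batch Adam step per
#' epoch. A per-epoch trace of the loss terms and (when clustering is
#' active) the bottleneck silhouette is recorded in `state$trace`.
#'
#' @param state a `training_state` from [build_autoencoder]. For survival
#'   losses it must carry the survival branch.
#' @param data a `multiomics_dataset` whose matrix is already scaled as the
#'   architecture expects (unit-norm for `baseline`, min-max for `custom`).
#' @param spec a [loss_spec].
#' @return the trained `training_state`; `state$sample_order` holds the
#'   presentation permutation, and for clustering losses
#'   `state$assignments`/`state$centroids` hold the final groups.
#' @export
train_autoencoder <- function(state, data, spec) {
  stopifnot(inherits(state, "training_state"), inherits(spec, "loss_spec"))
  X <- if (inherits(data, "multiomics_dataset")) data$matrix else data
  surv <- if (inherits(data, "multiomics_dataset")) data$survival else NULL
  if (spec$uses_survival && is.null(state$Ws)) {
    stopf("loss %s needs a survival branch; build with survival_branch = TRUE", spec$name)
  }
  if (spec$uses_survival && is.null(surv)) stopf("survival loss needs clinical data")
  if ((spec$uses_survival || spec$uses_clustering) &&
      !is.infinite(state$arch$batch_size) && state$arch$batch_size < nrow(X)) {
    stopf("survival/clustering losses require full-batch training")
  }
  perm <- seq_len(nrow(X))
  so <- NULL
  if (spec$uses_survival) {
    so <- survival_order(surv$time, surv$event)
    perm <- so$perm
  }
  Xo <- X[perm, , drop = FALSE]
  if (spec$uses_clustering) {
    state <- warmup_and_seed_centroids(state, Xo)
  }
  state <- run_epochs(state, Xo, spec, epochs = state$arch$epochs, so = so)
  state$sample_order <- perm
  ## map training-order assignments back to the dataset's sample order
  if (!is.null(state$assignments)) {
    inv <- integer(length(perm))
    inv[perm] <- seq_along(perm)
    state$assignments_data_order <- state$assignments[inv]
  }
  state
}
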