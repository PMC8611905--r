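# Small architectures (overriding the fixed hidden widths) keep these
# structural tests fast; full-size training behaviour is covered by the
# pipeline and acceptance tests.

tiny_arch <- function(variant = "custom", epochs = 5L) {
  arch <- architecture_spec(variant, epochs = epochs)
  arch$hidden_dims <- c(16L, 4L, 16L)
  arch$bottleneck <- 4L
  arch
}

tiny_data <- function(n = 24, p = 10, seed = 8) {
  g <- generate_multiomics(synthetic_spec(
    n_samples = n, block_widths = c(p - 4, 2, 2), informative_per_block = c(3, 1, 1),
    seed = seed))
  scale_minmax(g$dataset)
}

test_that("architecture variants carry the documented hyper-parameters", {
  b <- architecture_spec("baseline")
  expect_equal(b$hidden_dims, c(500L, 100L, 500L))
  expect_equal(b$activation, "tanh")
  expect_equal(b$dropout, 0.5)
  expect_equal(b$l1_kernel, 1e-3)
  expect_equal(b$l2_activity, 1e-4)
  expect_equal(b$optimizer, "sgd")
  expect_equal(b$batch_size, 1)
  expect_equal(b$epochs, 10L)
  cu <- architecture_spec("custom")
  expect_equal(cu$hidden_dims, c(1000L, 100L, 1000L))
  expect_equal(cu$activation, "sigmoid")
  expect_true(is.infinite(cu$batch_size))
  expect_equal(cu$optimizer, "adam")
  expect_equal(cu$epochs, 40L)
  expect_equal(cu$bottleneck, 100L)
})

test_that("building is reproducible and the survival branch is optional", {
  arch <- tiny_arch()
  s1 <- build_autoencoder(arch, 10, seed = 4, survival_branch = TRUE)
  s2 <- build_autoencoder(arch, 10, seed = 4, survival_branch = TRUE)
  expect_identical(s1$W, s2$W)
  expect_identical(s1$Ws, s2$Ws)
  s3 <- build_autoencoder(arch, 10, seed = 5, survival_branch = FALSE)
  expect_null(s3$Ws)
  expect_false(identical(s1$W[[1]], s3$W[[1]]))
  expect_equal(dim(s1$W[[1]]), c(10, 16))
  expect_equal(dim(s1$W[[2]]), c(16, 4))
  expect_error(build_autoencoder(arch, 2, seed = 1), "at least")
})

test_that("encoding is deterministic, shaped n x bottleneck, and finite", {
  d <- tiny_data()
  st <- build_autoencoder(tiny_arch(), ncol(d$matrix), seed = 1)
  B <- encode(st, d$matrix)
  expect_equal(dim(B), c(24, 4))
  expect_identical(encode(st, d$matrix), B)
  expect_true(all(is.finite(encode(st, matrix(0, 3, ncol(d$matrix))))))
})

test_that("furthest-pair seeding matches a brute-force oracle and ties break low", {
  set.seed(12)
  B <- matrix(rnorm(30 * 8), 30, 8)
  fp <- survclustae:::farthest_pair(B)
  D <- as.matrix(dist(B))
  expect_equal(D[fp[1], fp[2]], max(D))
  # 1-D positions {0, 1, 10}: seeds are points 1 and 3; point at 1 joins seed 0
  B1 <- matrix(c(0, 1, 10), 3, 1)
  expect_equal(survclustae:::farthest_pair(B1), c(1L, 3L))
  # duplicated farthest pairs -> lexicographically smallest pair
  B2 <- matrix(c(0, 10, 0, 10), 4, 1)
  expect_equal(survclustae:::farthest_pair(B2), c(1L, 2L))

  d <- tiny_data()
  st <- build_autoencoder(tiny_arch(), ncol(d$matrix), seed = 2)
  st <- warmup_and_seed_centroids(st, d$matrix)
  Bw <- encode(st, d$matrix)
  fpw <- survclustae:::farthest_pair(Bw)
  expect_equal(st$centroids, Bw[fpw, , drop = FALSE])
  expect_equal(st$assignments,
               unname(apply(survclustae:::centroid_sqdist(Bw, st$centroids), 1, which.min)))
})

test_that("training descends, is deterministic, and respects the survival ordering", {
  d <- tiny_data()
  st <- build_autoencoder(tiny_arch(epochs = 10L), ncol(d$matrix), seed = 3)
  st <- train_autoencoder(st, d, loss_spec("MSE"))
  expect_lt(st$trace$loss[10], st$trace$loss[1])

  st2 <- build_autoencoder(tiny_arch(epochs = 10L), ncol(d$matrix), seed = 3)
  st2 <- train_autoencoder(st2, d, loss_spec("MSE"))
  expect_identical(st$W, st2$W)

  sts <- build_autoencoder(tiny_arch(epochs = 4L), ncol(d$matrix), seed = 3,
                           survival_branch = TRUE)
  sts <- train_autoencoder(sts, d, loss_spec("L_RS"))
  expect_equal(sts$sample_order, order(d$survival$time, decreasing = TRUE))
  expect_equal(nrow(sts$trace), 4)
  expect_error(train_autoencoder(build_autoencoder(tiny_arch(), ncol(d$matrix), seed = 1),
                                 d, loss_spec("L_RS")), "survival branch")
})

test_that("centroid mean-update never increases within-assignment SSE on a frozen encoder", {
  d <- tiny_data(n = 40)
  st <- build_autoencoder(tiny_arch(), ncol(d$matrix), seed = 6)
  st <- warmup_and_seed_centroids(st, d$matrix)
  B <- encode(st, d$matrix)
  sse <- function(cen, asg) sum((B - cen[asg, , drop = FALSE])^2)
  before <- sse(st$centroids, st$assignments)
  st2 <- survclustae:::refresh_centroids(st, d$matrix)
  mid <- sse(st2$centroids, st$assignments)      # mean update, old groups
  after <- sse(st2$centroids, st2$assignments)   # after reassignment
  expect_lte(mid, before + 1e-10)
  expect_lte(after, mid + 1e-10)
})

test_that("clustering losses keep final assignments consistent with final centroids", {
  d <- tiny_data(n = 30)
  st <- build_autoencoder(tiny_arch(epochs = 6L), ncol(d$matrix), seed = 7)
  st <- train_autoencoder(st, d, loss_spec("L_RC"))
  B <- encode(st, d$matrix)
  cl <- labels_from_centroids(B, centroid_state(st$centroids, st$assignments_data_order))
  expect_equal(cl$labels, st$assignments_data_order)
  expect_equal(nrow(st$trace), 6)
  expect_true(all(is.finite(st$trace$clustering)))
})
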