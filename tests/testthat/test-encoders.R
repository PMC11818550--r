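test_that("attention normalisation is a softmax over the neighbourhood", {
  expect_equal(gat_normalize(rep(0.7, 5)), rep(0.2, 5))
  expect_equal(gat_normalize(3.2), 1)
  set.seed(41)
  for (i in 1:20) {
    e <- stats::rnorm(sample(2:8, 1), sd = 3)
    a <- gat_normalize(e)
    expect_equal(a, exp(e) / sum(exp(e)), tolerance = 1e-6)
    expect_equal(sum(a), 1, tolerance = 1e-12)
    expect_true(all(a >= 0))
  }
})

test_that("raw attention logits follow the additive form", {
  set.seed(42)
  W <- matrix(stats::rnorm(12), 3, 4)
  a_src <- stats::rnorm(4); a_dst <- stats::rnorm(4)
  vi <- stats::rnorm(3); vj <- stats::rnorm(3)
  raw <- sum(a_src * as.numeric(vi %*% W)) + sum(a_dst * as.numeric(vj %*% W))
  want <- if (raw > 0) raw else 0.2 * raw
  expect_equal(gat_attention(vi, vj, W, a_src, a_dst), want)
})

uniform_gat_params <- function(d, heads = 1L) {
  # zero attention vectors give uniform weights over each neighbourhood
  list(W = replicate(heads, diag(d), simplify = FALSE),
       a_src = replicate(heads, numeric(d), simplify = FALSE),
       a_dst = replicate(heads, numeric(d), simplify = FALSE),
       n_heads = heads, leaky_slope = 0.2)
}

test_that("attention updates reduce to neighbourhood means under uniform attention", {
  # single node with only its self-loop: output is relu of its own feature
  p <- uniform_gat_params(2)
  v <- matrix(c(1.5, -0.5), 1)
  expect_equal(gat_update(v, matrix(integer(0), 0, 2), p),
               matrix(c(1.5, 0), 1))
  # two connected nodes: each output is the mean of both inputs, then relu
  X <- matrix(c(1, 3, 2, -6), 2)
  out <- gat_update(X, cbind(1L, 2L), p)
  expect_equal(out, matrix(c(2, 2, 0, 0), 2))
})

test_that("attention rows sum to one on random graphs", {
  set.seed(43)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    g <- random_graph(n)
    d <- 4
    p <- gat_layer_params <- hetdta:::gat_layer_params(d, 4, 2L)
    X <- matrix(stats::rnorm(n * d), n)
    M <- (g$A + diag(n)) > 0
    fw <- hetdta:::gat_layer_forward(X, M, p)
    for (h in 1:2)
      expect_equal(unname(rowSums(fw$cache$heads[[h]]$alpha)), rep(1, n),
                   tolerance = 1e-6)
  }
})

test_that("graph-isomorphism update is (1+eps)*self + neighbour sum through the MLP", {
  p <- gin_identity_params(1)
  X <- matrix(c(1, 2, 3), 3)
  edges <- rbind(c(1L, 2L), c(1L, 3L))
  out <- gin_update(X, edges, p)
  expect_equal(out[1, ], 6)        # 1 + 2 + 3
  expect_equal(out[2, ], 3)        # 2 + 1
  iso <- gin_update(matrix(5, 1), matrix(integer(0), 0, 2), p)
  expect_equal(as.numeric(iso), 5)  # isolated node unchanged
})

test_that("GIN with eps 0 and identity MLP equals (A+I)X exactly", {
  set.seed(44)
  for (i in 1:20) {
    n <- sample(3:9, 1)
    g <- random_graph(n)
    X <- abs(matrix(stats::rnorm(n * 3), n))  # nonnegative so relu is inert
    out <- gin_update(X, g$edges, gin_identity_params(3))
    expect_equal(out, (g$A + diag(n)) %*% X, tolerance = 1e-6)
  }
})

test_that("encoder updates are permutation-equivariant", {
  set.seed(45)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    g <- random_graph(n)
    X <- matrix(stats::rnorm(n * 3), n)
    perm <- sample(n)
    # permuted edge list under the relabeling perm[old] = new
    pe <- if (nrow(g$edges)) cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]) else g$edges
    Xp <- X; Xp[perm, ] <- X
    pg <- hetdta:::gin_layer_params(3, 5)
    o1 <- gin_update(X, g$edges, pg)
    o2 <- gin_update(Xp, pe, pg)
    expect_equal(o2[perm, , drop = FALSE], o1, tolerance = 1e-10)
    pa <- hetdta:::gat_layer_params(3, 4, 2L)
    a1 <- gat_update(X, g$edges, pa)
    a2 <- gat_update(Xp, pe, pa)
    expect_equal(a2[perm, , drop = FALSE], a1, tolerance = 1e-10)
  }
})

test_that("self-attention pooling retains the ceiling(ratio*N) top-scoring nodes", {
  X <- matrix(stats::rnorm(961 * 2), 961)
  pool <- sag_pool(X, matrix(0, 961, 961), 0.5, c(1, 0))
  expect_equal(pool$k, 481L)
  expect_equal(nrow(pool$X_new), 481L)
  pool10 <- sag_pool(matrix(1, 10, 1), matrix(0, 10, 10), 0.5, 1)
  expect_equal(pool10$k, 5L)
})

test_that("pooling keeps the top-k by score and induces the subgraph adjacency", {
  n <- 8
  X <- matrix(seq_len(n), n, 1)
  # edgeless graph: the score convolution reduces to X %*% w, so scores are
  # strictly increasing with node index and the last k nodes are kept
  A <- matrix(0, n, n)
  pool <- sag_pool(X, A, 0.5, 1)
  expect_equal(pool$kept_indices, 5:8)
  expect_equal(pool$A_new, A[5:8, 5:8])
  expect_equal(pool$X_new, X[5:8, , drop = FALSE] * tanh(pool$scores[5:8]))
  set.seed(46)
  for (i in 1:10) {
    m <- sample(3:12, 1)
    ratio <- stats::runif(1, 0.2, 1)
    g <- random_graph(m)
    Xr <- matrix(stats::rnorm(m * 2), m)
    pr <- sag_pool(Xr, g$A, ratio, stats::rnorm(2))
    expect_lte(length(pr$kept_indices), ceiling(ratio * m))
    expect_equal(pr$A_new, g$A[pr$kept_indices, pr$kept_indices, drop = FALSE])
  }
})

test_that("global average pooling is the per-graph mean", {
  expect_equal(global_average_pool(matrix(c(3, 7), 1)), matrix(c(3, 7), 1))
  two <- matrix(c(0, 2, 2, 0), 2, byrow = TRUE)
  expect_equal(as.numeric(global_average_pool(two)), c(1, 1))
  set.seed(47)
  X <- matrix(stats::rnorm(18), 9)
  memb <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  got <- global_average_pool(X, memb)
  for (gix in 1:3)
    expect_equal(unname(got[gix, ]), colMeans(X[memb == gix, , drop = FALSE]))
  expect_error(global_average_pool(matrix(numeric(0), 0, 2)), "empty")
})
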