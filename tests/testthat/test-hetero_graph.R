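test_that("block adjacency assembles [[Sd, B], [Bt, Sp]] correctly", {
  Sd <- diag(2); B <- matrix(1:6 / 10, 2, 3); Sp <- diag(3)
  A <- assemble_adjacency(Sd, B, Sp)
  expect_equal(dim(A), c(5L, 5L))
  expect_equal(A[1:2, 3:5], B)
  expect_equal(A[3:5, 1:2], t(B))
  A0 <- assemble_adjacency(Sd, matrix(0, 2, 3), Sp)
  expect_equal(A0, diag(5))
  expect_error(assemble_adjacency(Sd, matrix(0, 3, 3), Sp), "incompatible")
  expect_error(assemble_adjacency(Sd, matrix(-1, 2, 3), Sp), "nonnegative")
})

test_that("assembled adjacency is symmetric whenever the blocks are", {
  set.seed(21)
  for (i in 1:10) {
    dr <- sample(2:5, 1); dp <- sample(2:5, 1)
    Sd <- matrix(stats::runif(dr^2), dr); Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
    Sp <- matrix(stats::runif(dp^2), dp); Sp <- (Sp + t(Sp)) / 2; diag(Sp) <- 1
    B <- matrix(stats::runif(dr * dp), dr)
    A <- assemble_adjacency(Sd, B, Sp)
    expect_identical(A, t(A))
  }
})

make_toy_hg <- function(dr = 2, dp = 3, seed = 1, w1 = 0.1, w2 = 0.1) {
  set.seed(seed)
  Sd <- matrix(stats::runif(dr^2), dr); Sd <- (Sd + t(Sd)) / 2; diag(Sd) <- 1
  Sp <- matrix(stats::runif(dp^2), dp); Sp <- (Sp + t(Sp)) / 2; diag(Sp) <- 1
  dimnames(Sd) <- list(paste0("d", 1:dr), paste0("d", 1:dr))
  dimnames(Sp) <- list(paste0("p", 1:dp), paste0("p", 1:dp))
  aff <- affinity_table(expand.grid(drug_id = rownames(Sd),
                                    protein_id = rownames(Sp),
                                    stringsAsFactors = FALSE)[1:4, ] |>
                          transform(value = stats::runif(4, 1, 9)))
  hetero_graph(Sd, Sp, aff, w1 = w1, w2 = w2)
}

test_that("dynamic thresholding prunes similarity blocks and leaves B alone", {
  hg <- make_toy_hg()
  hg$Sd[1, 2] <- hg$Sd[2, 1] <- 0.3
  A <- dynamic_threshold(hg, w1 = 0.1, w2 = 0.1)
  expect_equal(A[1, 2], 0.2)
  hg$Sd[1, 2] <- hg$Sd[2, 1] <- 0.05
  A <- dynamic_threshold(hg, w1 = 0.1, w2 = 0.1)
  expect_equal(A[1, 2], 0)
  # the affinity block passes through untouched for random thresholds
  for (w in c(0, 0.3, 0.9)) {
    A <- dynamic_threshold(hg, w1 = w, w2 = w)
    expect_equal(A[1:2, 3:5], hg$B)
  }
  # zero thresholds are the identity on the assembled adjacency
  A0 <- dynamic_threshold(hg, w1 = 0, w2 = 0)
  expect_equal(A0, assemble_adjacency(hg$Sd, hg$B, hg$Sp))
})

test_that("raising a threshold never adds edges (monotone sparsification)", {
  hg <- make_toy_hg(dr = 6, dp = 7, seed = 4)
  ws <- seq(0, 1, by = 0.05)
  edges_d <- vapply(ws, function(w)
    sum(dynamic_threshold(hg, w1 = w, w2 = 0.2)[1:6, 1:6] != 0), numeric(1))
  expect_true(all(diff(edges_d) <= 0))
  edges_p <- vapply(ws, function(w)
    sum(dynamic_threshold(hg, w1 = 0.2, w2 = w)[7:13, 7:13] != 0), numeric(1))
  expect_true(all(diff(edges_p) <= 0))
})

test_that("binarize marks exactly the nonzero entries", {
  expect_equal(binarize(matrix(0, 3, 3)), matrix(0, 3, 3))
  m <- matrix(c(0, 0.2, -1, 0), 2)
  expect_equal(binarize(m), matrix(c(0, 1, 1, 0), 2))
  set.seed(2)
  r <- matrix(stats::rnorm(25) * (stats::runif(25) < 0.5), 5)
  expect_equal(binarize(r), (r != 0) * 1)
})

test_that("hetero node features are [type one-hot | binarized adjacency]", {
  hg <- make_toy_hg()
  A <- dynamic_threshold(hg)
  psi <- hetero_features(hg, A)
  expect_equal(dim(psi), c(5L, 7L))
  expect_equal(unname(psi[, 1]), c(1, 1, 0, 0, 0))
  expect_equal(unname(psi[, 2]), c(0, 0, 1, 1, 1))
  expect_equal(unname(rowSums(psi[, 1:2])), rep(1, 5))
  expect_equal(psi[, 3:7], binarize(A), ignore_attr = TRUE)
})

test_that("B is populated from the supplied records only (leakage control)", {
  hg <- make_toy_hg()   # only the first 4 of 6 pairs carry affinities
  # min-max scaling sends the weakest supplied pair to exactly 0, so three
  # of the four supplied pairs carry positive weight; unsupplied pairs stay 0
  expect_equal(sum(hg$B > 0), 3L)
  expect_true(all(hg$B >= 0 & hg$B <= 1))
  set.seed(1)
  Sd <- diag(2); dimnames(Sd) <- list(c("d1", "d2"), c("d1", "d2"))
  Sp <- diag(2); dimnames(Sp) <- list(c("p1", "p2"), c("p1", "p2"))
  aff <- affinity_table(data.frame(drug_id = c("d1", "d2"),
                                   protein_id = c("p1", "p2"),
                                   value = c(3, 7)))
  hb <- hetero_graph(Sd, Sp, aff, b_scale = "binary")
  expect_equal(unname(hb$B), matrix(c(1, 0, 0, 1), 2))  # exactly the records
  hr <- hetero_graph(Sd, Sp, aff, b_scale = "raw")
  expect_equal(unname(hr$B), matrix(c(3, 0, 0, 7), 2))
})

test_that("graph convolution matches the dense normalised-propagation oracle", {
  # no off-diagonal edges, identity weights: propagation is the identity
  H <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(gcn_propagate(matrix(0, 2, 2), H, diag(2)), H)
  # two nodes, one unit edge: both outputs average to 2
  A <- matrix(c(0, 1, 1, 0), 2)
  H2 <- matrix(c(1, 3), 2, 1)
  expect_equal(gcn_propagate(A, H2, diag(1)), matrix(c(2, 2), 2, 1))
  set.seed(31)
  for (i in 1:50) {
    n <- sample(5:10, 1)
    g <- random_graph(n)
    H <- matrix(stats::rnorm(n * 4), n)
    W <- matrix(stats::rnorm(16), 4)
    expect_equal(gcn_propagate(g$A, H, W), gcn_dense_oracle(g$A, H, W),
                 tolerance = 1e-6)
  }
  expect_error(gcn_propagate(matrix(NA_real_, 2, 2), H, diag(2)), "NA")
})

test_that("threshold gradients match finite differences on a toy hetero graph", {
  spec <- synthetic_spec(n_drugs = 2, n_proteins = 3, seq_len_range = c(8L, 10L),
                         seed = 5)
  ds <- synthetic_dataset(spec)
  cfg <- tiny_config(seed = 5)
  sp <- make_splits(ds$affinities, 5)
  tr <- sp$folds[[1]]$train
  inp <- hetdta:::prepare_inputs(ds$drugs, ds$proteins, ds$affinities, cfg, tr,
                                 ds$Sd, ds$Sp)
  di <- match(ds$affinities$drug_id, inp$drug_ids)
  pi_ <- match(ds$affinities$protein_id, inp$protein_ids)
  set.seed(9)
  params <- hetdta:::init_params(cfg, list(F_d = inp$F_d, F_p = inp$F_p,
                                           dr = 2, dp = 3), 2)
  y <- ds$affinities$value
  lossf <- function(p) {
    fw <- hetdta:::model_forward(p, inp, cfg, di[tr], pi_[tr], training = FALSE)
    mean((y[tr] - fw$yhat)^2)
  }
  fw <- hetdta:::model_forward(params, inp, cfg, di[tr], pi_[tr], training = FALSE)
  lg <- hetdta:::loss_and_grad(fw$yhat, fw$yraw, y[tr], "regression")
  gr <- hetdta:::model_backward(params, inp, cfg, fw$cache, lg$dyraw)
  eps <- 1e-5
  for (wname in c("w1", "w2")) {
    pp <- params; pp$hetero[[wname]] <- pp$hetero[[wname]] + eps
    pm <- params; pm$hetero[[wname]] <- pm$hetero[[wname]] - eps
    num <- (lossf(pp) - lossf(pm)) / (2 * eps)
    expect_lt(abs(num - gr$hetero[[wname]]), 1e-4)
  }
})
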