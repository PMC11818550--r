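# Per-molecule encoders, exposed as pure functions of (graph, parameters):
# graph attention (drug atom graphs), graph isomorphism updates (protein
# residue graphs), self-attention top-k pooling, global average pooling.

leaky_relu <- function(x, slope = 0.2) x * (slope + (1 - slope) * (x > 0))

#' Raw attention coefficient between two nodes
#'
#' Computes `e_ij = LeakyReLU(a_src . (W v_i) + a_dst . (W v_j))`, the
#' standard additive graph-attention score with the attention vector split
#' into source and destination halves.
#'
#' @param vi,vj node feature vectors.
#' @param W linear transform matrix (`length(vi)` rows).
#' @param a_src,a_dst attention weight vectors (`ncol(W)` long).
#' @param leaky_slope negative slope of the LeakyReLU, default 0.2.
#' @return the scalar attention logit `e_ij`.
#' @export
gat_attention <- function(vi, vj, W, a_src, a_dst, leaky_slope = 0.2) {
  zi <- as.numeric(vi %*% W); zj <- as.numeric(vj %*% W)
  leaky_relu(sum(a_src * zi) + sum(a_dst * zj), leaky_slope)
}

#' Softmax normalisation of attention logits over a neighbourhood
#'
#' @param e numeric vector of attention logits over `N(i)`.
#' @return nonnegative weights summing to 1.
#' @export
gat_normalize <- function(e) {
  x <- exp(e - max(e))
  x / sum(x)
}

# initialise GAT layer parameters (Glorot uniform)
gat_layer_params <- function(d_in, d_out, n_heads = 2L, leaky_slope = 0.2) {
  stopifnot(d_out %% n_heads == 0L)
  dh <- d_out %/% n_heads
  glorot <- function(r, c) matrix(stats::runif(r * c, -1, 1) * sqrt(6 / (r + c)), r, c)
  list(W = lapply(seq_len(n_heads), function(h) glorot(d_in, dh)),
       a_src = lapply(seq_len(n_heads), function(h) as.numeric(glorot(dh, 1))),
       a_dst = lapply(seq_len(n_heads), function(h) as.numeric(glorot(dh, 1))),
       n_heads = n_heads, leaky_slope = leaky_slope)
}

# dense GAT layer forward with cache for the backward pass.
# M: N x N logical mask of the self-looped neighbourhood.
gat_layer_forward <- function(X, M, params, final_relu = TRUE) {
  N <- nrow(X)
  heads <- vector("list", params$n_heads)
  outs <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    Z <- X %*% params$W[[h]]
    ss <- as.numeric(Z %*% params$a_src[[h]])
    sd <- as.numeric(Z %*% params$a_dst[[h]])
    Epre <- outer(ss, rep(1, N)) + outer(rep(1, N), sd)
    E <- leaky_relu(Epre, params$leaky_slope)
    E[!M] <- -Inf
    E <- E - apply(E, 1, max)
    ex <- exp(E); ex[!M] <- 0
    alpha <- ex / rowSums(ex)
    outs[[h]] <- alpha %*% Z
    heads[[h]] <- list(Z = Z, alpha = alpha, Epre = Epre)
  }
  O <- do.call(cbind, outs)
  out <- if (final_relu) relu(O) else O
  list(out = out, cache = list(X = X, M = M, heads = heads, O = O,
                               final_relu = final_relu, params = params))
}

gat_layer_backward <- function(dOut, cache) {
  p <- cache$params
  dO <- if (cache$final_relu) dOut * (cache$O > 0) else dOut
  dh <- ncol(cache$heads[[1]]$Z)
  dX <- matrix(0, nrow(cache$X), ncol(cache$X))
  gW <- vector("list", p$n_heads); gas <- vector("list", p$n_heads)
  gad <- vector("list", p$n_heads)
  for (h in seq_len(p$n_heads)) {
    hc <- cache$heads[[h]]
    dOh <- dO[, ((h - 1) * dh + 1):(h * dh), drop = FALSE]
    dalpha <- tcrossprod(dOh, hc$Z)
    dZ <- crossprod(hc$alpha, dOh)
    srow <- rowSums(hc$alpha * dalpha)
    dE <- hc$alpha * (dalpha - srow)
    dEraw <- dE * ifelse(hc$Epre > 0, 1, p$leaky_slope)
    dEraw[!cache$M] <- 0
    dss <- rowSums(dEraw); dsd <- colSums(dEraw)
    dZ <- dZ + outer(dss, p$a_src[[h]]) + outer(dsd, p$a_dst[[h]])
    gas[[h]] <- as.numeric(crossprod(hc$Z, dss))
    gad[[h]] <- as.numeric(crossprod(hc$Z, dsd))
    gW[[h]] <- crossprod(cache$X, dZ)
    dX <- dX + tcrossprod(dZ, p$W[[h]])
  }
  list(dX = dX, W = gW, a_src = gas, a_dst = gad)
}

#' One graph-attention update of node features
#'
#' Multi-head additive attention over each node's self-looped neighbourhood
#' followed by an attention-weighted sum, heads concatenated, ReLU applied.
#' Isolated nodes attend only to themselves.
#'
#' @param node_features `N x F` matrix.
#' @param edges undirected edge list (`m x 2` integer matrix).
#' @param params parameter list as produced by the fitted model: per-head
#'   `W`, `a_src`, `a_dst`, plus `n_heads` and `leaky_slope`.
#' @return the updated `N x d_out` feature matrix.
#' @export
gat_update <- function(node_features, edges, params) {
  N <- nrow(node_features)
  A <- matrix(0, N, N)
  if (length(edges)) {
    A[edges] <- 1; A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  M <- (A + diag(N)) > 0
  gat_layer_forward(node_features, M, params)$out
}

# ---- GIN ----

gin_layer_params <- function(d_in, d_out, epsilon = 0) {
  glorot <- function(r, c) matrix(stats::runif(r * c, -1, 1) * sqrt(6 / (r + c)), r, c)
  list(epsilon = epsilon, W1 = glorot(d_in, d_out), b1 = numeric(d_out),
       W2 = glorot(d_out, d_out), b2 = numeric(d_out))
}

gin_layer_forward <- function(X, A, params, final_relu = TRUE) {
  M <- (1 + params$epsilon) * X + A %*% X
  H1p <- add_bias(M %*% params$W1, params$b1)
  H1 <- relu(H1p)
  H2p <- add_bias(H1 %*% params$W2, params$b2)
  out <- if (final_relu) relu(H2p) else H2p
  list(out = out, cache = list(X = X, A = A, M = M, H1p = H1p, H1 = H1,
                               H2p = H2p, final_relu = final_relu, params = params))
}

gin_layer_backward <- function(dOut, cache) {
  p <- cache$params
  dH2p <- if (cache$final_relu) dOut * (cache$H2p > 0) else dOut
  gW2 <- crossprod(cache$H1, dH2p)
  gb2 <- colSums(dH2p)
  dH1 <- tcrossprod(dH2p, p$W2)
  dH1p <- dH1 * (cache$H1p > 0)
  gW1 <- crossprod(cache$M, dH1p)
  gb1 <- colSums(dH1p)
  dM <- tcrossprod(dH1p, p$W1)
  dX <- (1 + p$epsilon) * dM + crossprod(cache$A, dM)
  geps <- sum(dM * cache$X)
  list(dX = dX, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, epsilon = geps)
}

#' One graph-isomorphism update of node features
#'
#' Per node: `MLP((1 + epsilon) * v_p + sum of neighbour features)`, the
#' sum-aggregation update with a learnable `epsilon` and a two-layer MLP.
#'
#' @param node_features `N x F` matrix.
#' @param edges undirected edge list (`m x 2` integer matrix).
#' @param params list with `epsilon`, `W1`, `b1`, `W2`, `b2`. Pass identity
#'   matrices / zero biases to inspect the raw aggregation.
#' @return the updated feature matrix.
#' @export
gin_update <- function(node_features, edges, params) {
  N <- nrow(node_features)
  A <- matrix(0, N, N)
  if (length(edges)) {
    A[edges] <- 1; A[edges[, c(2, 1), drop = FALSE]] <- 1
  }
  gin_layer_forward(node_features, A, params)$out
}

# ---- self-attention top-k pooling ----

#' Self-attention top-k graph pooling
#'
#' Scores every node with a single graph-convolution
#' (`s = D^{-1/2}(A+I)D^{-1/2} X w`), keeps the `k = ceiling(ratio * N)`
#' highest-scoring nodes, gates their features by `tanh(s)`, and induces the
#' subgraph adjacency on the kept nodes.
#'
#' @param X `N x F` node features.
#' @param A `N x N` symmetric adjacency (no self-loops).
#' @param ratio retention fraction in `(0, 1]`.
#' @param w_score score weight vector (`F` long, or `F x 1`).
#' @return list with `scores`, `kept_indices`, `X_new`, `A_new`, `ratio`, `k`.
#' @export
sag_pool <- function(X, A, ratio, w_score) {
  N <- nrow(X)
  stopifnot(N >= 1L, ratio > 0, ratio <= 1)
  w <- matrix(as.numeric(w_score), ncol = 1)
  An <- normalize_adjacency(A)$An
  s <- as.numeric(An %*% X %*% w)
  k <- as.integer(ceiling(ratio * N))
  idx <- order(s, decreasing = TRUE)[seq_len(k)]
  idx <- sort(idx)  # preserve node order within the retained set
  g <- tanh(s)
  list(scores = s, kept_indices = idx,
       X_new = X[idx, , drop = FALSE] * g[idx],
       A_new = A[idx, idx, drop = FALSE], ratio = ratio, k = k)
}

sag_pool_backward <- function(dXnew, X, An, w_score, pool) {
  idx <- pool$kept_indices
  g <- tanh(pool$scores)
  dX <- matrix(0, nrow(X), ncol(X))
  dX[idx, ] <- dXnew * g[idx]
  dg_kept <- rowSums(dXnew * X[idx, , drop = FALSE])
  ds <- numeric(nrow(X))
  ds[idx] <- dg_kept * (1 - g[idx]^2)
  AntDs <- crossprod(An, ds)
  dw <- crossprod(X, AntDs)
  dX <- dX + tcrossprod(AntDs, matrix(as.numeric(w_score), ncol = 1))
  list(dX = dX, w_score = as.numeric(dw))
}

#' Global average pooling over one or more graphs
#'
#' @param node_features stacked node-feature matrix.
#' @param membership integer vector assigning each row to a graph (default:
#'   all rows one graph).
#' @return a `n_graphs x F` matrix of per-graph means.
#' @export
global_average_pool <- function(node_features, membership = NULL) {
  if (nrow(node_features) == 0L) stop_hetdta("cannot pool an empty graph")
  if (is.null(membership)) return(row_mean(node_features))
  membership <- as.integer(membership)
  counts <- table(membership)
  sums <- rowsum(node_features, membership)
  sums / as.numeric(counts)
}
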