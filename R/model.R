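# End-to-end affinity model: per-molecule encoders + dynamic heterogeneous
# graph + fusion + prediction head, trained by hand-written reverse-mode
# differentiation with Adam. All layer caches live for exactly one step.

#' Model configuration
#'
#' Defaults follow the published training protocol: Adam at learning rate
#' 5e-4, batch size 512, dropout 0.2/0.3/0.5 on the heterogeneous / graph /
#' fingerprint branches, embedding sizes 256/1024/128 (heterogeneous, graph,
#' fingerprint), fully connected head 1024/512/1, thresholds started at
#' 0.1/0.1, with 200 epochs as the desk-run default (4000 for full-scale
#' runs). `profile = "desk"` scales the widths and batch down
#' (64/64/64, head 256/128/1, batch 64) for laptop-sized fixtures; the
#' methods vignette motivates these sizes.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size over affinity pairs.
#' @param learning_rate Adam learning rate.
#' @param dropout named triple `c(hetero=, graph=, ecfp=)` in `[0, 1)`.
#' @param hetero_dim,graph_dim,ecfp_dim embedding widths.
#' @param fc_dims three head widths, last must be 1.
#' @param w_init initial `c(w1, w2)` edge thresholds.
#' @param pool_ratio self-attention pooling retention fraction.
#' @param gin_layers,gat_layers,gat_heads encoder depths / head count.
#' @param leaky_slope LeakyReLU slope inside attention.
#' @param fp_radius,fp_bits fingerprint parameters.
#' @param contact_threshold contact-probability cut-off for residue graphs.
#' @param window sequence-window fallback width when no contact map exists.
#' @param seed integer seed controlling splits, initialisation, batch order.
#' @param task `"regression"` or `"classification"`.
#' @param ablation `"full"`, `"no_hetero_gin"` (drop the heterogeneous
#'   branch) or `"no_hetero_gcn"` (drop it and replace the protein
#'   GIN + pooling encoder with a plain two-layer GCN).
#' @param b_scale affinity-block scaling, see [hetero_graph()].
#' @param b_leak if `TRUE`, populate the affinity block from all records
#'   including held-out test pairs (the literal, leaky variant); default
#'   `FALSE` uses training records only.
#' @param patience early-stopping patience on validation MSE (`Inf` disables).
#' @param profile `"paper"` or `"desk"`.
#' @return a `hetdta_config` list.
#' @export
hetdta_config <- function(epochs = 200L, batch_size = NULL, learning_rate = 5e-4,
                          dropout = c(hetero = 0.2, graph = 0.3, ecfp = 0.5),
                          hetero_dim = NULL, graph_dim = NULL, ecfp_dim = NULL,
                          fc_dims = NULL, w_init = c(0.1, 0.1), pool_ratio = 0.5,
                          gin_layers = 3L, gat_layers = 2L, gat_heads = 2L,
                          leaky_slope = 0.2, fp_radius = 2L, fp_bits = 1024L,
                          contact_threshold = 0.5, window = 3L, seed = 1L,
                          task = c("regression", "classification"),
                          ablation = c("full", "no_hetero_gin", "no_hetero_gcn"),
                          b_scale = "minmax", b_leak = FALSE, patience = 50L,
                          profile = c("paper", "desk")) {
  task <- match.arg(task)
  ablation <- match.arg(ablation)
  profile <- match.arg(profile)
  desk <- profile == "desk"
  cfg <- list(
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size %||% if (desk) 64L else 512L),
    learning_rate = learning_rate,
    dropout = dropout,
    hetero_dim = as.integer(hetero_dim %||% if (desk) 64L else 256L),
    graph_dim = as.integer(graph_dim %||% if (desk) 64L else 1024L),
    ecfp_dim = as.integer(ecfp_dim %||% if (desk) 64L else 128L),
    fc_dims = as.integer(fc_dims %||% if (desk) c(256L, 128L, 1L) else c(1024L, 512L, 1L)),
    w_init = w_init, pool_ratio = pool_ratio,
    gin_layers = as.integer(gin_layers), gat_layers = as.integer(gat_layers),
    gat_heads = as.integer(gat_heads), leaky_slope = leaky_slope,
    fp_radius = as.integer(fp_radius), fp_bits = as.integer(fp_bits),
    contact_threshold = contact_threshold, window = as.integer(window),
    seed = as.integer(seed), task = task, ablation = ablation,
    b_scale = b_scale, b_leak = isTRUE(b_leak), patience = patience,
    profile = profile)
  stopifnot(all(cfg$dropout >= 0 & cfg$dropout < 1),
            cfg$fc_dims[3] == 1L, cfg$graph_dim %% cfg$gat_heads == 0L,
            cfg$pool_ratio > 0, cfg$pool_ratio <= 1)
  class(cfg) <- "hetdta_config"
  cfg
}

glorot <- function(r, c) matrix(stats::runif(r * c, -1, 1) * sqrt(6 / (r + c)), r, c)

init_params <- function(cfg, meta, y_mean = 0) {
  dg <- cfg$graph_dim; dh <- cfg$hetero_dim; de <- cfg$ecfp_dim
  use_het <- cfg$ablation == "full"
  p <- list()
  p$ecfp <- list(W = glorot(cfg$fp_bits, de), b = numeric(de))
  gat_in <- c(meta$F_d, rep(dg, cfg$gat_layers - 1L))
  p$gat <- lapply(seq_len(cfg$gat_layers), function(l) {
    gp <- gat_layer_params(gat_in[l], dg, cfg$gat_heads, cfg$leaky_slope)
    gp[c("W", "a_src", "a_dst")]
  })
  if (cfg$ablation == "no_hetero_gcn") {
    p$pgcn <- list(W1 = glorot(meta$F_p, dg), W2 = glorot(dg, dg))
  } else {
    gin_in <- c(meta$F_p, rep(dg, cfg$gin_layers - 1L))
    p$gin <- lapply(seq_len(cfg$gin_layers), function(l)
      gin_layer_params(gin_in[l], dg, epsilon = 0))
    p$pool <- list(w = glorot(dg, 1))
  }
  if (use_het) {
    p$hetero <- list(
      W0 = glorot(2L + meta$dr + meta$dp, dh), W1 = glorot(dh, dh),
      w1 = cfg$w_init[1], w2 = cfg$w_init[2],
      M1d = glorot(dh, dh), b1d = numeric(dh), M2d = glorot(dh, dh), b2d = numeric(dh),
      M1p = glorot(dh, dh), b1p = numeric(dh), M2p = glorot(dh, dh), b2p = numeric(dh))
  }
  d_drug <- de + dg + if (use_het) dh else 0L
  d_prot <- dg + if (use_het) dh else 0L
  fc <- cfg$fc_dims
  p$head <- list(W1 = glorot(d_drug + d_prot, fc[1]), b1 = numeric(fc[1]),
                 W2 = glorot(fc[1], fc[2]), b2 = numeric(fc[2]),
                 W3 = glorot(fc[2], 1), b3 = y_mean)
  p
}

dropout_mask <- function(dim1, dim2, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(dim1 * dim2) >= p) / (1 - p), dim1, dim2)
}
apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

# ---- per-branch forward/backward ----
#
# Molecule graphs are processed as one block-diagonal stack (the usual GNN
# batching trick): node features of all graphs are row-bound, adjacency is
# sparse block-diagonal, and graph membership drives pooling via rowsum().

# sum v by integer segment id into a length-n vector
segment_sum <- function(v, idx, n) {
  out <- numeric(n)
  rs <- rowsum(v, idx)
  out[as.integer(rownames(rs))] <- rs
  out
}

# stacked multi-head attention layer; recv/send are directed edge endpoint
# vectors (receiver aggregates over senders = neighbours plus itself)
gat_stack_forward <- function(X, st, pl, cfg) {
  N <- nrow(X)
  heads <- vector("list", cfg$gat_heads)
  outs <- vector("list", cfg$gat_heads)
  for (h in seq_len(cfg$gat_heads)) {
    Z <- X %*% pl$W[[h]]
    ss <- as.numeric(Z %*% pl$a_src[[h]])
    sd <- as.numeric(Z %*% pl$a_dst[[h]])
    epre <- ss[st$recv] + sd[st$send]
    e <- leaky_relu(epre, cfg$leaky_slope)
    # every node receives from itself, so the clamped un-shifted softmax is
    # safe: exp() stays in (4e-18, 2e17) and denominators are positive
    ex <- exp(pmin(pmax(e, -40), 40))
    den <- segment_sum(ex, st$recv, N)
    alpha <- ex / den[st$recv]
    P <- Matrix::sparseMatrix(i = st$recv, j = st$send, x = alpha, dims = c(N, N))
    outs[[h]] <- as.matrix(P %*% Z)
    heads[[h]] <- list(Z = Z, alpha = alpha, epre = epre, P = P)
  }
  out <- relu_inplace(do.call(cbind, outs))
  list(out = out, cache = list(X = X, out = out, heads = heads))
}

gat_stack_backward <- function(dOut, cache, st, pl, cfg) {
  dO <- relu_mask_inplace(dOut, cache$out)
  N <- nrow(cache$X)
  dh <- ncol(cache$heads[[1]]$Z)
  dX <- matrix(0, N, ncol(cache$X))
  gW <- vector("list", cfg$gat_heads)
  gas <- vector("list", cfg$gat_heads); gad <- vector("list", cfg$gat_heads)
  for (h in seq_len(cfg$gat_heads)) {
    hc <- cache$heads[[h]]
    dOh <- dO[, ((h - 1) * dh + 1):(h * dh), drop = FALSE]
    dZ <- as.matrix(Matrix::crossprod(hc$P, dOh))
    dalpha <- rowSums(dOh[st$recv, , drop = FALSE] * hc$Z[st$send, , drop = FALSE])
    sseg <- segment_sum(hc$alpha * dalpha, st$recv, N)
    dE <- hc$alpha * (dalpha - sseg[st$recv])
    dEraw <- dE * (cfg$leaky_slope + (1 - cfg$leaky_slope) * (hc$epre > 0))
    dss <- segment_sum(dEraw, st$recv, N)
    dsd <- segment_sum(dEraw, st$send, N)
    dZ <- dZ + outer(dss, pl$a_src[[h]]) + outer(dsd, pl$a_dst[[h]])
    gas[[h]] <- as.numeric(crossprod(hc$Z, dss))
    gad[[h]] <- as.numeric(crossprod(hc$Z, dsd))
    gW[[h]] <- crossprod(cache$X, dZ)
    dX <- dX + tcrossprod(dZ, pl$W[[h]])
  }
  list(dX = dX, W = gW, a_src = gas, a_dst = gad)
}

drug_branch_forward <- function(pgat, st, cfg) {
  X <- st$X
  lc <- vector("list", cfg$gat_layers)
  for (l in seq_len(cfg$gat_layers)) {
    fw <- gat_stack_forward(X, st, pgat[[l]], cfg)
    lc[[l]] <- fw$cache
    X <- fw$out
  }
  GD <- rowsum(X, st$m) / st$counts
  list(GD = GD, layers = lc)
}

drug_branch_backward <- function(dGD, fwd, st, pgat, cfg) {
  dX <- dGD[st$m, , drop = FALSE] / st$counts[st$m]
  g <- vector("list", cfg$gat_layers)
  for (l in rev(seq_len(cfg$gat_layers))) {
    bw <- gat_stack_backward(dX, fwd$layers[[l]], st, pgat[[l]], cfg)
    g[[l]] <- bw[c("W", "a_src", "a_dst")]
    dX <- bw$dX
  }
  g
}

protein_branch_forward <- function(params, st, cfg) {
  if (cfg$ablation == "no_hetero_gcn") {
    P1 <- as.matrix(st$An_sp %*% st$X)
    H1 <- relu_inplace(P1 %*% params$pgcn$W1)
    P2 <- as.matrix(st$An_sp %*% H1)
    H2 <- relu_inplace(P2 %*% params$pgcn$W2)
    GP <- rowsum(H2, st$m) / st$counts
    return(list(GP = GP, cache = list(P1 = P1, H1 = H1, P2 = P2, H2 = H2)))
  }
  X <- st$X
  lc <- vector("list", cfg$gin_layers)
  for (l in seq_len(cfg$gin_layers)) {
    M <- (1 + params$gin[[l]]$epsilon) * X + as.matrix(st$A_sp %*% X)
    H1 <- bias_relu_inplace(M %*% params$gin[[l]]$W1, params$gin[[l]]$b1)
    out <- bias_relu_inplace(H1 %*% params$gin[[l]]$W2, params$gin[[l]]$b2)
    lc[[l]] <- list(X = X, M = M, H1 = H1, out = out)
    X <- out
  }
  s <- as.numeric(st$An_sp %*% X %*% params$pool$w)
  g <- tanh(s)
  n_graphs <- length(st$counts)
  GP <- matrix(0, n_graphs, ncol(X))
  kept <- vector("list", n_graphs)
  ks <- integer(n_graphs)
  for (i in seq_len(n_graphs)) {
    nodes <- st$nodes[[i]]
    k <- as.integer(ceiling(cfg$pool_ratio * length(nodes)))
    sel <- nodes[order(s[nodes], decreasing = TRUE)[seq_len(k)]]
    kept[[i]] <- sel
    ks[i] <- k
    GP[i, ] <- colSums(X[sel, , drop = FALSE] * g[sel]) / k
  }
  list(GP = GP, cache = list(layers = lc, X_last = X, s = s, g = g,
                             kept = kept, ks = ks))
}

protein_branch_backward <- function(dGP, fwd, st, params, cfg) {
  if (cfg$ablation == "no_hetero_gcn") {
    ci <- fwd$cache
    dH2 <- dGP[st$m, , drop = FALSE] / st$counts[st$m]
    dpre2 <- relu_mask_inplace(dH2, ci$H2)
    gW2 <- crossprod(ci$P2, dpre2)
    dH1 <- as.matrix(Matrix::crossprod(st$An_sp, tcrossprod(dpre2, params$pgcn$W2)))
    dpre1 <- relu_mask_inplace(dH1, ci$H1)
    gW1 <- crossprod(ci$P1, dpre1)
    return(list(pgcn = list(W1 = gW1, W2 = gW2)))
  }
  ci <- fwd$cache
  X <- ci$X_last
  N <- nrow(X)
  dX <- matrix(0, N, ncol(X))
  ds <- numeric(N)
  for (i in seq_along(ci$kept)) {
    sel <- ci$kept[[i]]
    dXnew <- matrix(dGP[i, ] / ci$ks[i], length(sel), ncol(X), byrow = TRUE)
    dX[sel, ] <- dX[sel, ] + dXnew * ci$g[sel]
    dg <- rowSums(dXnew * X[sel, , drop = FALSE])
    ds[sel] <- ds[sel] + dg * (1 - ci$g[sel]^2)
  }
  AntDs <- as.matrix(Matrix::crossprod(st$An_sp, ds))
  gpool <- crossprod(X, AntDs)
  dX <- dX + tcrossprod(AntDs, matrix(as.numeric(params$pool$w), ncol = 1))
  ggin <- vector("list", cfg$gin_layers)
  for (l in rev(seq_len(cfg$gin_layers))) {
    lc <- ci$layers[[l]]
    pl <- params$gin[[l]]
    dH2p <- relu_mask_inplace(dX, lc$out)
    gW2 <- crossprod(lc$H1, dH2p); gb2 <- colSums(dH2p)
    dH1p <- relu_mask_inplace(tcrossprod(dH2p, pl$W2), lc$H1)
    gW1 <- crossprod(lc$M, dH1p); gb1 <- colSums(dH1p)
    dM <- tcrossprod(dH1p, pl$W1)
    dX <- (1 + pl$epsilon) * dM + as.matrix(Matrix::crossprod(st$A_sp, dM))
    ggin[[l]] <- list(epsilon = sum(dM * lc$X), W1 = gW1, b1 = gb1,
                      W2 = gW2, b2 = gb2)
  }
  list(gin = ggin, pool = list(w = gpool))
}

mlp2_forward <- function(H, W1, b1, W2, b2) {
  Z1 <- bias_relu_inplace(H %*% W1, b1)
  Z2 <- bias_relu_inplace(Z1 %*% W2, b2)
  list(out = Z2, cache = list(H = H, Z1 = Z1, Z2 = Z2))
}
mlp2_backward <- function(dZ2, cache, W1, W2) {
  dpre2 <- relu_mask_inplace(dZ2, cache$Z2)
  gW2 <- crossprod(cache$Z1, dpre2); gb2 <- colSums(dpre2)
  dpre1 <- relu_mask_inplace(tcrossprod(dpre2, W2), cache$Z1)
  gW1 <- crossprod(cache$H, dpre1); gb1 <- colSums(dpre1)
  list(dH = tcrossprod(dpre1, W1), W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

hetero_branch_forward <- function(ph, hg, cfg, training, masks) {
  A_thr <- dynamic_threshold(hg, ph$w1, ph$w2)
  psiH <- hetero_features(hg, A_thr)
  nz <- normalize_adjacency(A_thr)
  P1 <- nz$An %*% psiH
  H1 <- relu_inplace(P1 %*% ph$W0)
  P2 <- nz$An %*% H1
  H2 <- relu_inplace(P2 %*% ph$W1)
  H2d <- apply_mask(H2, masks$hetero)
  dr <- hg$dr
  md <- mlp2_forward(H2d[seq_len(dr), , drop = FALSE], ph$M1d, ph$b1d, ph$M2d, ph$b2d)
  mp <- mlp2_forward(H2d[(dr + 1):nrow(H2d), , drop = FALSE], ph$M1p, ph$b1p, ph$M2p, ph$b2p)
  list(Td = md$out, Tp = mp$out,
       cache = list(A_thr = A_thr, psiH = psiH, nz = nz, P1 = P1,
                    H1 = H1, P2 = P2, H2 = H2, md = md$cache,
                    mp = mp$cache, mask = masks$hetero, dr = dr))
}

# backward through normalisation An = D^{-1/2} (A + I) D^{-1/2} given dL/dAn
normalization_backward <- function(G, nz) {
  dis <- nz$dis
  dA_hat <- G * outer(dis, dis)
  GA <- G * nz$A_hat
  dd <- -0.5 * nz$d^(-1.5) *
    (rowSums(sweep(GA, 2, dis, "*")) + colSums(GA * dis))
  dA_hat + matrix(dd, nrow = length(dd), ncol = length(dd))
}

hetero_branch_backward <- function(dTd, dTp, ph, hg, cache) {
  bd <- mlp2_backward(dTd, cache$md, ph$M1d, ph$M2d)
  bp <- mlp2_backward(dTp, cache$mp, ph$M1p, ph$M2p)
  dH2d <- rbind(bd$dH, bp$dH)
  dH2 <- apply_mask(dH2d, cache$mask)
  dpre2 <- relu_mask_inplace(dH2, cache$H2)
  gW1 <- crossprod(cache$P2, dpre2)
  dP2 <- tcrossprod(dpre2, ph$W1)
  dAn <- tcrossprod(dP2, cache$H1)
  dpre1 <- relu_mask_inplace(crossprod(cache$nz$An, dP2), cache$H1)
  gW0 <- crossprod(cache$P1, dpre1)
  dP1 <- tcrossprod(dpre1, ph$W0)
  dAn <- dAn + tcrossprod(dP1, cache$psiH)
  dA <- normalization_backward(dAn, cache$nz)
  dr <- hg$dr; np <- hg$dp
  drug_blk <- dA[seq_len(dr), seq_len(dr), drop = FALSE]
  prot_blk <- dA[(dr + 1):(dr + np), (dr + 1):(dr + np), drop = FALSE]
  gw1 <- -sum(drug_blk * (hg$Sd - ph$w1 > 0))
  gw2 <- -sum(prot_blk * (hg$Sp - ph$w2 > 0))
  list(W0 = gW0, W1 = gW1, w1 = gw1, w2 = gw2,
       M1d = bd$W1, b1d = bd$b1, M2d = bd$W2, b2d = bd$b2,
       M1p = bp$W1, b1p = bp$b1, M2p = bp$W2, b2p = bp$b2)
}

# ---- full model ----

model_forward <- function(params, inp, cfg, di, pi_, training = FALSE) {
  dr <- nrow(inp$FP); np <- length(inp$pstack$counts)
  masks <- list(ecfp = NULL, graph_d = NULL, graph_p = NULL, hetero = NULL)
  if (training) {
    masks$ecfp <- dropout_mask(dr, cfg$ecfp_dim, cfg$dropout[["ecfp"]])
    masks$graph_d <- dropout_mask(dr, cfg$graph_dim, cfg$dropout[["graph"]])
    masks$graph_p <- dropout_mask(np, cfg$graph_dim, cfg$dropout[["graph"]])
    if (cfg$ablation == "full")
      masks$hetero <- dropout_mask(dr + np, cfg$hetero_dim, cfg$dropout[["hetero"]])
  }
  Eact <- bias_relu_inplace(inp$FP %*% params$ecfp$W, params$ecfp$b)
  E <- apply_mask(Eact, masks$ecfp)
  dfw <- drug_branch_forward(params$gat, inp$dstack, cfg)
  GD <- apply_mask(dfw$GD, masks$graph_d)
  pfw <- protein_branch_forward(params, inp$pstack, cfg)
  GP <- apply_mask(pfw$GP, masks$graph_p)
  het <- NULL
  if (cfg$ablation == "full")
    het <- hetero_branch_forward(params$hetero, inp$hg, cfg, training, masks)
  Hd <- if (is.null(het)) cbind(E[di, , drop = FALSE], GD[di, , drop = FALSE])
        else cbind(E[di, , drop = FALSE], GD[di, , drop = FALSE],
                   het$Td[di, , drop = FALSE])
  Ht <- if (is.null(het)) GP[pi_, , drop = FALSE]
        else cbind(GP[pi_, , drop = FALSE], het$Tp[pi_, , drop = FALSE])
  Hcat <- cbind(Hd, Ht)
  hp <- params$head
  Z1 <- bias_relu_inplace(Hcat %*% hp$W1, hp$b1)
  Z2 <- bias_relu_inplace(Z1 %*% hp$W2, hp$b2)
  yraw <- as.numeric(Z2 %*% hp$W3 + hp$b3)
  yhat <- if (cfg$task == "classification") sigmoid(yraw) else yraw
  list(yhat = yhat, yraw = yraw,
       cache = list(Eact = Eact, masks = masks, dfw = dfw,
                    pfw = pfw, het = het, Hcat = Hcat, Z1 = Z1,
                    Z2 = Z2, di = di, pi_ = pi_, dr = dr, np = np))
}

# scatter per-pair gradient rows back to per-molecule rows
scatter_rows <- function(dRows, idx, n) {
  out <- matrix(0, n, ncol(dRows))
  rs <- rowsum(dRows, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

model_backward <- function(params, inp, cfg, cache, dyraw) {
  ca <- cache
  hp <- params$head
  gW3 <- crossprod(ca$Z2, dyraw); gb3 <- sum(dyraw)
  dpre2 <- relu_mask_inplace(tcrossprod(dyraw, hp$W3), ca$Z2)
  gW2 <- crossprod(ca$Z1, dpre2); gb2 <- colSums(dpre2)
  dpre1 <- relu_mask_inplace(tcrossprod(dpre2, hp$W2), ca$Z1)
  gW1 <- crossprod(ca$Hcat, dpre1); gb1 <- colSums(dpre1)
  dHcat <- tcrossprod(dpre1, hp$W1)

  de <- cfg$ecfp_dim; dg <- cfg$graph_dim
  use_het <- cfg$ablation == "full"
  dh <- if (use_het) cfg$hetero_dim else 0L
  d_drug <- de + dg + dh
  dHd <- dHcat[, seq_len(d_drug), drop = FALSE]
  dHt <- dHcat[, (d_drug + 1):ncol(dHcat), drop = FALSE]

  dE_rows <- scatter_rows(dHd[, seq_len(de), drop = FALSE], ca$di, ca$dr)
  dGD_rows <- scatter_rows(dHd[, de + seq_len(dg), drop = FALSE], ca$di, ca$dr)
  dGP_rows <- scatter_rows(dHt[, seq_len(dg), drop = FALSE], ca$pi_, ca$np)

  g <- list(head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                        W3 = gW3, b3 = gb3))

  dEact <- apply_mask(dE_rows, ca$masks$ecfp)
  dpreE <- relu_mask_inplace(dEact, ca$Eact)
  g$ecfp <- list(W = crossprod(inp$FP, dpreE), b = colSums(dpreE))

  dGD <- apply_mask(dGD_rows, ca$masks$graph_d)
  g$gat <- drug_branch_backward(dGD, ca$dfw, inp$dstack, params$gat, cfg)

  dGP <- apply_mask(dGP_rows, ca$masks$graph_p)
  g <- c(g, protein_branch_backward(dGP, ca$pfw, inp$pstack, params, cfg))

  if (use_het) {
    dTd <- scatter_rows(dHd[, de + dg + seq_len(dh), drop = FALSE], ca$di, ca$dr)
    dTp <- scatter_rows(dHt[, dg + seq_len(dh), drop = FALSE], ca$pi_, ca$np)
    g$hetero <- hetero_branch_backward(dTd, dTp, params$hetero, inp$hg, ca$het$cache)
  }
  g
}

# loss + gradient of the raw (pre-link) output for a batch
loss_and_grad <- function(yhat, yraw, y, task) {
  n <- length(y)
  if (task == "classification") {
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    list(loss = -mean(y * log(p) + (1 - y) * log(1 - p)),
         dyraw = matrix((yhat - y) / n, ncol = 1))
  } else {
    list(loss = mean((y - yhat)^2),
         dyraw = matrix(2 * (yhat - y) / n, ncol = 1))
  }
}

# rebuild the nested parameter list from the flat vector (fast relist)
unflatten_params <- function(theta, skel) {
  pos <- 0L
  rec <- function(sk) {
    if (is.list(sk)) return(lapply(sk, rec))
    n <- length(sk)
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    dm <- dim(sk)
    if (!is.null(dm)) dim(out) <- dm
    out
  }
  rec(skel)
}

# reorder a gradient tree to mirror the parameter tree (name-aware)
align_tree <- function(ref, g) {
  if (!is.list(ref)) return(g)
  nm <- names(ref)
  if (is.null(nm)) return(mapply(align_tree, ref, g, SIMPLIFY = FALSE))
  out <- lapply(nm, function(n) align_tree(ref[[n]], g[[n]]))
  names(out) <- nm
  out
}

# Adam runs on the flat parameter vector; the nested list is rebuilt with
# relist() against the parameter skeleton once per step
adam_init <- function(params) {
  n <- length(unlist(params, use.names = FALSE))
  list(m = numeric(n), v = numeric(n), t = 0L)
}

# ---- data preparation ----

# stack a list of molecular_graph objects block-diagonally
stack_graphs <- function(graphs) {
  ns <- vapply(graphs, function(g) g$n_nodes, integer(1))
  off <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  N <- nrow(X)
  m <- rep(seq_along(graphs), ns)
  ga <- integer(0); gb <- integer(0)
  for (i in seq_along(graphs)) {
    e <- graphs[[i]]$edges
    if (length(e)) {
      ga <- c(ga, e[, 1] + off[i]); gb <- c(gb, e[, 2] + off[i])
    }
  }
  A_sp <- Matrix::sparseMatrix(i = c(ga, gb), j = c(gb, ga), x = 1,
                               dims = c(N, N))
  A1 <- A_sp + Matrix::Diagonal(N)
  dis <- 1 / sqrt(Matrix::rowSums(A1))
  An_sp <- Matrix::Diagonal(x = dis) %*% A1 %*% Matrix::Diagonal(x = dis)
  list(X = X, m = m, counts = ns, nodes = split(seq_len(N), m),
       A_sp = A_sp, An_sp = An_sp,
       recv = c(ga, gb, seq_len(N)), send = c(gb, ga, seq_len(N)))
}

prepare_inputs <- function(drugs, proteins, affinities, cfg, train_idx,
                           Sd = NULL, Sp = NULL) {
  FP <- do.call(rbind, lapply(drugs$smiles, morgan_fingerprint,
                              radius = cfg$fp_radius, n_bits = cfg$fp_bits))
  rownames(FP) <- drugs$id
  dstack <- stack_graphs(lapply(drugs$smiles, smiles_to_graph))
  cmaps <- proteins$contact_map %||% vector("list", nrow(proteins))
  pstack <- stack_graphs(lapply(seq_len(nrow(proteins)), function(i)
    protein_graph(proteins$sequence[i], cmaps[[i]],
                  threshold = cfg$contact_threshold, window = cfg$window)))
  hg <- NULL
  if (cfg$ablation == "full") {
    if (is.null(Sd)) Sd <- drug_similarity_matrix(drugs, cfg$fp_radius, cfg$fp_bits)
    if (is.null(Sp)) Sp <- protein_similarity_matrix(proteins)
    b_records <- if (cfg$b_leak) affinities else affinities[train_idx, , drop = FALSE]
    hg <- hetero_graph(Sd, Sp, affinity_table(b_records, task = attr(affinities, "task")),
                       w1 = cfg$w_init[1], w2 = cfg$w_init[2], b_scale = cfg$b_scale)
  }
  list(FP = FP, dstack = dstack, pstack = pstack, hg = hg,
       drug_ids = drugs$id, protein_ids = proteins$id,
       F_d = ncol(dstack$X), F_p = ncol(pstack$X))
}

#' Fit the heterogeneous-graph affinity model
#'
#' Builds fingerprints, per-molecule graphs, similarity matrices and the
#' dataset-level heterogeneous graph (affinity block from training records
#' only), then trains the full network with Adam under the settings in
#' `config`. Returns a fitted model with standard accessor methods
#' (`print`, `summary`, `predict`, `plot`, `coef`, `residuals`).
#'
#' @param drugs data.frame with columns `id`, `smiles`.
#' @param proteins data.frame with columns `id`, `sequence` and optionally a
#'   `contact_map` list column.
#' @param affinities an `affinity_table` (see [affinity_table()]).
#' @param config a [hetdta_config()].
#' @param splits a [make_splits()] plan; built from `config$seed` if omitted.
#' @param fold which cross-validation fold supplies the validation set.
#' @param Sd,Sp precomputed similarity matrices (recomputed if omitted).
#' @param verbose print a progress line every 25 epochs.
#' @return an object of class `hetdta`.
#' @export
hetdta <- function(drugs, proteins, affinities, config = hetdta_config(),
                   splits = NULL, fold = 1L, Sd = NULL, Sp = NULL,
                   verbose = FALSE) {
  stopifnot(inherits(affinities, "affinity_table"))
  if (is.null(splits)) splits <- make_splits(affinities, config$seed)
  fold_def <- splits$folds[[fold]]
  train_idx <- fold_def$train
  val_idx <- fold_def$validation
  test_idx <- splits$test_indices

  inp <- prepare_inputs(drugs, proteins, affinities, config, train_idx, Sd, Sp)
  di <- match(affinities$drug_id, inp$drug_ids)
  pi_ <- match(affinities$protein_id, inp$protein_ids)
  y <- affinities$value

  set.seed(config$seed)
  meta <- list(F_d = inp$F_d, F_p = inp$F_p,
               dr = length(inp$drug_ids), dp = length(inp$protein_ids))
  y_mean <- if (config$task == "regression") mean(y[train_idx]) else 0
  params <- init_params(config, meta, y_mean = y_mean)
  skeleton <- params
  theta <- unlist(params, use.names = FALSE)
  state <- adam_init(params)

  n_epoch <- config$epochs
  hist <- data.frame(epoch = seq_len(n_epoch), train_loss = NA_real_,
                     val_mse = NA_real_, w1 = NA_real_, w2 = NA_real_,
                     drug_edges = NA_integer_)
  best <- list(val = Inf, params = params, epoch = 0L)
  wait <- 0L

  for (ep in seq_len(n_epoch)) {
    perm <- sample(train_idx)
    nb <- ceiling(length(perm) / config$batch_size)
    ep_loss <- 0
    for (b in seq_len(nb)) {
      ii <- perm[((b - 1L) * config$batch_size + 1L):min(b * config$batch_size, length(perm))]
      fw <- model_forward(params, inp, config, di[ii], pi_[ii], training = TRUE)
      lg <- loss_and_grad(fw$yhat, fw$yraw, y[ii], config$task)
      if (!is.finite(lg$loss))
        stop_hetdta("training diverged (non-finite loss) at epoch ", ep,
                    ", batch ", b, "; w1=", signif(get_w(params, "w1"), 4),
                    " w2=", signif(get_w(params, "w2"), 4))
      grads <- align_tree(params, model_backward(params, inp, config, fw$cache, lg$dyraw))
      state$t <- state$t + 1L
      adam_update_inplace(theta, state$m, state$v,
                          unlist(grads, use.names = FALSE),
                          config$learning_rate, 0.9, 0.999, state$t, 1e-8)
      params <- unflatten_params(theta, skeleton)
      ep_loss <- ep_loss + lg$loss * length(ii)
    }
    hist$train_loss[ep] <- ep_loss / length(perm)
    hist$w1[ep] <- get_w(params, "w1"); hist$w2[ep] <- get_w(params, "w2")
    if (config$ablation == "full") {
      A_thr <- dynamic_threshold(inp$hg, params$hetero$w1, params$hetero$w2)
      hist$drug_edges[ep] <- sum(A_thr[seq_len(meta$dr), seq_len(meta$dr)] != 0)
    }
    if (length(val_idx)) {
      fv <- model_forward(params, inp, config, di[val_idx], pi_[val_idx],
                          training = FALSE)
      hist$val_mse[ep] <- mean((y[val_idx] - fv$yhat)^2)
      if (hist$val_mse[ep] < best$val) {
        best <- list(val = hist$val_mse[ep], params = params, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) {
          hist <- hist[seq_len(ep), , drop = FALSE]
          break
        }
      }
    }
    if (verbose && ep %% 25L == 0L)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, hist$train_loss[ep],
                      hist$val_mse[ep]))
  }

  final_params <- if (length(val_idx) && is.finite(best$val)) best$params else params
  evaluate_split <- function(idx) {
    if (!length(idx)) return(NULL)
    fw <- model_forward(final_params, inp, config, di[idx], pi_[idx], training = FALSE)
    list(pred = fw$yhat, report = metric_report(y[idx], fw$yhat, config$task))
  }
  ev_train <- evaluate_split(train_idx)
  ev_val <- evaluate_split(val_idx)
  ev_test <- evaluate_split(test_idx)

  structure(list(params = final_params, config = config, inputs = inp,
                 affinities = affinities, splits = splits, fold = fold,
                 history = hist, best_epoch = best$epoch,
                 train = ev_train, validation = ev_val, test = ev_test,
                 di = di, pi_ = pi_, y = y),
            class = "hetdta")
}

get_w <- function(params, which) {
  if (is.null(params$hetero)) NA_real_ else params$hetero[[which]]
}

#' Cross-validated fit over all five folds
#'
#' @inheritParams hetdta
#' @return list of fitted `hetdta` objects (one per fold) plus a `summary`
#'   data.frame of per-fold validation and test metrics.
#' @export
hetdta_cv <- function(drugs, proteins, affinities, config = hetdta_config(),
                      splits = NULL, Sd = NULL, Sp = NULL) {
  if (is.null(splits)) splits <- make_splits(affinities, config$seed)
  fits <- lapply(seq_along(splits$folds), function(k)
    hetdta(drugs, proteins, affinities, config, splits, fold = k, Sd = Sd, Sp = Sp))
  summ <- do.call(rbind, lapply(seq_along(fits), function(k) {
    f <- fits[[k]]
    data.frame(fold = k,
               val_mse = f$validation$report$mse %||% NA_real_,
               test_mse = f$test$report$mse %||% NA_real_,
               test_ci = f$test$report$ci %||% NA_real_)
  }))
  list(fits = fits, summary = summ)
}

# ---- S3 methods ----

#' @export
print.hetdta <- function(x, ...) {
  cat("Heterogeneous-graph drug-target affinity model\n")
  cat(sprintf("  variant: %s | task: %s | profile: %s\n",
              x$config$ablation, x$config$task, x$config$profile))
  cat(sprintf("  %d drugs x %d proteins, %d affinity records\n",
              length(x$inputs$drug_ids), length(x$inputs$protein_ids),
              attr(x$affinities, "n")))
  cat(sprintf("  trained %d epochs (best validation at %d)\n",
              nrow(x$history), x$best_epoch))
  if (!is.null(x$test)) {
    r <- x$test$report
    if (x$config$task == "regression")
      cat(sprintf("  test: MSE %.4f | CI %.4f | rm2 %.4f (n=%d)\n",
                  r$mse, r$ci, r$rm2, r$n))
    else
      cat(sprintf("  test: AUROC %.4f | precision %.4f | recall %.4f (n=%d)\n",
                  r$auroc, r$precision, r$recall, r$n))
  }
  invisible(x)
}

#' @export
summary.hetdta <- function(object, ...) {
  out <- list(config = object$config,
              history = utils::tail(object$history, 1),
              train = object$train$report,
              validation = object$validation$report,
              test = object$test$report,
              w1 = get_w(object$params, "w1"),
              w2 = get_w(object$params, "w2"))
  class(out) <- "summary.hetdta"
  out
}

#' @export
print.summary.hetdta <- function(x, ...) {
  fmt <- function(r) if (is.null(r)) "-" else
    paste(sprintf("%s=%.4f", setdiff(names(r), "n"),
                  unlist(r[setdiff(names(r), "n")])), collapse = " ")
  cat("train:     ", fmt(x$train), "\n")
  cat("validation:", fmt(x$validation), "\n")
  cat("test:      ", fmt(x$test), "\n")
  if (!is.na(x$w1)) cat(sprintf("thresholds: w1=%.4f w2=%.4f\n", x$w1, x$w2))
  invisible(x)
}

#' Predict affinities for drug-protein pairs
#'
#' @param object a fitted `hetdta` model.
#' @param pairs data.frame with columns `drug_id`, `protein_id`; ids must be
#'   among the molecules the model was fitted with. Defaults to the held-out
#'   test pairs.
#' @param ... unused.
#' @return numeric vector of predicted affinities (probabilities for
#'   classification).
#' @export
predict.hetdta <- function(object, pairs = NULL, ...) {
  if (is.null(pairs)) {
    idx <- object$splits$test_indices
    di <- object$di[idx]; pi_ <- object$pi_[idx]
  } else {
    di <- match(pairs$drug_id, object$inputs$drug_ids)
    pi_ <- match(pairs$protein_id, object$inputs$protein_ids)
    if (anyNA(di)) stop_hetdta("unknown drug id(s): ",
                               paste(unique(pairs$drug_id[is.na(di)]), collapse = ", "))
    if (anyNA(pi_)) stop_hetdta("unknown protein id(s): ",
                                paste(unique(pairs$protein_id[is.na(pi_)]), collapse = ", "))
  }
  model_forward(object$params, object$inputs, object$config, di, pi_,
                training = FALSE)$yhat
}

#' @export
coef.hetdta <- function(object, ...) {
  c(w1 = get_w(object$params, "w1"), w2 = get_w(object$params, "w2"))
}

#' @export
residuals.hetdta <- function(object, split = c("test", "train", "validation"), ...) {
  split <- match.arg(split)
  idx <- switch(split, test = object$splits$test_indices,
                train = object$splits$folds[[object$fold]]$train,
                validation = object$splits$folds[[object$fold]]$validation)
  ev <- object[[if (split == "train") "train" else split]]
  object$y[idx] - ev$pred
}

#' @export
plot.hetdta <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", main = "training loss", ...)
  if (any(is.finite(h$val_mse)))
    graphics::lines(h$epoch, h$val_mse, lty = 2)
  if (all(is.finite(h$w1))) {
    graphics::plot(h$epoch, h$w1, type = "l", xlab = "epoch", ylab = "threshold",
                   ylim = range(c(h$w1, h$w2)), main = "edge thresholds")
    graphics::lines(h$epoch, h$w2, lty = 2)
  } else {
    graphics::plot.new()
  }
  invisible(x)
}
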