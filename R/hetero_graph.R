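# Dataset-level heterogeneous graph: block adjacency [[Sd, B], [Bt, Sp]],
# learnable edge thresholds on the similarity blocks, derived node features,
# and symmetric-normalised graph-convolution propagation.

#' Assemble the heterogeneous block adjacency
#'
#' Stacks the drug-drug similarity block, the drug-protein affinity block and
#' the protein-protein similarity block into
#' `[[Sd, B], [t(B), Sp]]` of side `dr + dp`.
#'
#' @param Sd `dr x dr` drug similarity matrix.
#' @param B `dr x dp` nonnegative affinity block.
#' @param Sp `dp x dp` protein similarity matrix.
#' @return the `(dr+dp) x (dr+dp)` adjacency; symmetric when `Sd`/`Sp` are.
#' @export
assemble_adjacency <- function(Sd, B, Sp) {
  dr <- nrow(Sd); dp <- nrow(Sp)
  if (ncol(Sd) != dr || ncol(Sp) != dp || nrow(B) != dr || ncol(B) != dp)
    stop_hetdta("block shapes incompatible: Sd ", dr, "x", ncol(Sd),
                ", B ", nrow(B), "x", ncol(B), ", Sp ", dp, "x", ncol(Sp))
  if (min(B) < 0) stop_hetdta("affinity block B must be nonnegative")
  rbind(cbind(unclass(Sd), B), cbind(t(B), unclass(Sp)))
}

#' Construct a heterogeneous drug-protein graph
#'
#' Bundles the similarity blocks, the affinity block and the learnable
#' thresholds `w1` (drug block) and `w2` (protein block). `B` is populated
#' from the supplied affinity records only — callers pass training-set
#' records so held-out test pairs stay structurally invisible — and is
#' min-max scaled to `[0, 1]` by default so all blocks share a comparable
#' weight range.
#'
#' @param Sd,Sp similarity matrices with drug/protein ids as dimnames.
#' @param affinities an `affinity_table` (training records only).
#' @param w1,w2 initial thresholds, default 0.1 each.
#' @param b_scale `"minmax"` (default), `"binary"` (1 for every observed
#'   pair) or `"raw"`.
#' @return a `hetero_graph` list: `Sd`, `Sp`, `B`, `w1`, `w2`, `dr`, `dp`,
#'   `drug_ids`, `protein_ids`, `D_onehot`.
#' @export
hetero_graph <- function(Sd, Sp, affinities, w1 = 0.1, w2 = 0.1,
                         b_scale = c("minmax", "binary", "raw")) {
  b_scale <- match.arg(b_scale)
  drug_ids <- rownames(Sd); protein_ids <- rownames(Sp)
  check_square_symmetric(unclass(Sd), "Sd")
  check_square_symmetric(unclass(Sp), "Sp")
  dr <- length(drug_ids); dp <- length(protein_ids)
  B <- matrix(0, dr, dp, dimnames = list(drug_ids, protein_ids))
  di <- match(affinities$drug_id, drug_ids)
  pi_ <- match(affinities$protein_id, protein_ids)
  if (anyNA(di) || anyNA(pi_))
    stop_hetdta("affinity records reference ids absent from the similarity matrices")
  v <- affinities$value
  v <- switch(b_scale,
    minmax = if (diff(range(v)) == 0) rep(1, length(v)) else (v - min(v)) / diff(range(v)),
    binary = rep(1, length(v)),
    raw = {
      if (min(v) < 0) stop_hetdta("raw B requires nonnegative affinities")
      v
    })
  B[cbind(di, pi_)] <- v
  D <- rbind(cbind(rep(1, dr), 0), cbind(0, rep(1, dp)))
  structure(list(Sd = unclass(Sd), Sp = unclass(Sp), B = B, w1 = w1, w2 = w2,
                 dr = dr, dp = dp, drug_ids = drug_ids,
                 protein_ids = protein_ids, D_onehot = D),
            class = "hetero_graph")
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat(sprintf("hetero_graph: %d drugs + %d proteins, %d observed pairs, w1=%.3g w2=%.3g\n",
              x$dr, x$dp, sum(x$B > 0), x$w1, x$w2))
  invisible(x)
}

#' Learnable edge thresholding of the heterogeneous adjacency
#'
#' Applies `ReLU(Sd - w1)` to the drug block and `ReLU(Sp - w2)` to the
#' protein block; the affinity block `B` passes through unchanged. Raising a
#' threshold prunes (never adds) similarity edges, and the operation is
#' differentiable in `w1`/`w2` almost everywhere.
#'
#' @param hg a `hetero_graph`.
#' @param w1,w2 thresholds; default the graph's current values.
#' @return the thresholded `(dr+dp)` square adjacency (no self-loops).
#' @export
dynamic_threshold <- function(hg, w1 = hg$w1, w2 = hg$w2) {
  assemble_adjacency(pmax(hg$Sd - w1, 0), hg$B, pmax(hg$Sp - w2, 0))
}

#' Binarize an adjacency
#'
#' Marks every nonzero entry as 1.
#'
#' @param A numeric matrix.
#' @return 0/1 matrix of the same shape.
#' @export
binarize <- function(A) (A != 0) * 1

#' Node features of the dynamic heterogeneous graph
#'
#' Concatenates the two-column drug/protein type indicator with the
#' binarized thresholded adjacency: shape `(dr+dp) x (2 + dr + dp)`. Drug
#' rows carry type `(1, 0)`, protein rows `(0, 1)`.
#'
#' @param hg a `hetero_graph`.
#' @param A_thr the thresholded adjacency from [dynamic_threshold()];
#'   recomputed from `hg` when omitted.
#' @return the node-feature matrix.
#' @export
hetero_features <- function(hg, A_thr = dynamic_threshold(hg)) {
  cbind(hg$D_onehot, binarize(A_thr))
}

# symmetric normalisation D^{-1/2} (A + I) D^{-1/2}; returns pieces needed
# for the backward pass as attributes-free list
normalize_adjacency <- function(A) {
  if (anyNA(A)) stop_hetdta("adjacency contains NA/NaN")
  A_hat <- A + diag(nrow(A))
  d <- rowSums(A_hat)
  dis <- 1 / sqrt(d)
  list(An = A_hat * outer(dis, dis), A_hat = A_hat, d = d, dis = dis)
}

#' One graph-convolution propagation step
#'
#' `H_out = sigma(D^{-1/2} (A + I) D^{-1/2} H W)` with weighted degrees of the
#' self-looped adjacency and ReLU activation (identity when
#' `activation = "linear"`).
#'
#' @param A weighted nonnegative adjacency without self-loops (added here).
#' @param H node-feature matrix.
#' @param W layer weight matrix.
#' @param activation `"relu"` or `"linear"`.
#' @return the propagated node-feature matrix.
#' @export
gcn_propagate <- function(A, H, W, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  nz <- normalize_adjacency(A)
  out <- nz$An %*% H %*% W
  if (activation == "relu") relu(out) else out
}
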