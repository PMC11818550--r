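# Independent oracles used across test files. These deliberately avoid the
# package's own code paths: brute-force enumeration, dense linear algebra,
# and explicit double loops.

# optimal global alignment score by exhaustive enumeration of all alignments
# (recursive over the three moves); only viable for very short sequences
nw_enumerate <- function(a, b, match, mismatch, gap) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

# concordance index by explicit double loop over ordered pairs
ci_brute <- function(y, yhat) {
  num <- 0; Z <- 0
  n <- length(y)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (y[i] > y[j]) {
      Z <- Z + 1
      d <- yhat[i] - yhat[j]
      num <- num + if (d > 0) 1 else if (d == 0) 0.5 else 0
    }
  }
  num / Z
}

# dense symmetric-normalised GCN propagation, written independently
gcn_dense_oracle <- function(A, H, W) {
  Ah <- A + diag(nrow(A))
  D <- diag(1 / sqrt(rowSums(Ah)))
  out <- D %*% Ah %*% D %*% H %*% W
  out * (out > 0)
}

# random undirected graph as an edge list + dense adjacency
random_graph <- function(n, p = 0.4) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[stats::runif(length(up)) < p]
  A[on] <- 1
  A <- A + t(A)
  idx <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
  list(A = A, edges = cbind(idx[, 1], idx[, 2]))
}

# random amino-acid sequence
random_aa <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L","M","N",
                 "P","Q","R","S","T","V","W","Y"), len, replace = TRUE),
        collapse = "")
}

# identity-MLP GIN parameters of the given width
gin_identity_params <- function(d) {
  list(epsilon = 0, W1 = diag(d), b1 = numeric(d), W2 = diag(d), b2 = numeric(d))
}
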