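# Per-molecule graphs: drug atom graphs from SMILES, protein residue graphs
# from contact maps (or a sequence-window fallback when no map is available).

ATOM_SYMBOLS <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
                  "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb",
                  "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge",
                  "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg",
                  "Pb", "Unknown")

STANDARD_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1,
                      Br = 1, I = 1, B = 3, Si = 4)

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y", "X")

AA_PROPERTY_SETS <- list(
  aliphatic   = c("A", "G", "I", "L", "P", "V"),
  aromatic    = c("F", "W", "Y", "H"),
  polar       = c("S", "T", "N", "Q", "C", "Y"),
  positive    = c("K", "R", "H"),
  negative    = c("D", "E"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
  small       = c("A", "G", "S", "C", "T", "P", "D", "N"))

new_molecular_graph <- function(node_features, edges, kind) {
  n <- nrow(node_features)
  if (length(edges)) {
    stopifnot(ncol(edges) == 2L)
    if (any(edges < 1L) || any(edges > n)) stop_hetdta("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) stop_hetdta("explicit self-loops are not stored")
  }
  structure(list(node_features = node_features, edges = edges, kind = kind,
                 n_nodes = n, n_edges = if (length(edges)) nrow(edges) else 0L),
            class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("molecular_graph (%s): %d nodes, %d undirected edges, %d features/node\n",
              x$kind, x$n_nodes, x$n_edges, ncol(x$node_features)))
  invisible(x)
}

# dense symmetric adjacency (no self-loops) from an edge list
graph_adjacency <- function(g) {
  A <- matrix(0, g$n_nodes, g$n_nodes)
  if (g$n_edges > 0) {
    A[g$edges] <- 1
    A[g$edges[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

one_hot <- function(value, levels) as.numeric(levels == value)

# clamp-to-top one-hot for small counts (degree, H count, valence)
count_one_hot <- function(k, max_k = 10L) {
  v <- numeric(max_k + 1L)
  v[min(k, max_k) + 1L] <- 1
  v
}

#' Convert a SMILES string to a drug atom graph
#'
#' Heavy atoms become nodes, chemical bonds become undirected edges. Node
#' features are a 78-dimensional vector in the GraphDTA convention: element
#' one-hot over 44 symbols, degree (0-10), attached hydrogens (0-10),
#' implicit valence (0-10), and an aromaticity flag. Hydrogen counts and
#' implicit valence are derived from standard element valences minus the
#' bond-order sum. Multi-fragment SMILES (salts, mixtures) are rejected.
#'
#' @param smiles a single-fragment SMILES string.
#' @return a `molecular_graph` of kind `"drug"`.
#' @export
smiles_to_graph <- function(smiles) {
  mol <- parse_smiles(smiles)
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)
  n <- nrow(ab)
  symbols <- sub("_[0-9]+$", "", rownames(ab))
  # bondless molecules yield a malformed placeholder bond block
  edges <- if (is.null(bb) || nrow(bb) == 0L || ncol(bb) < 3L) {
    matrix(integer(0), 0, 2)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]))
  }
  orders <- if (nrow(edges)) as.numeric(bb[, 3]) else numeric(0)

  # connectivity: reject multi-fragment input loudly
  if (n > 1L) {
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    adj <- lapply(seq_len(n), function(i) integer(0))
    for (k in seq_len(nrow(edges))) {
      adj[[edges[k, 1]]] <- c(adj[[edges[k, 1]]], edges[k, 2])
      adj[[edges[k, 2]]] <- c(adj[[edges[k, 2]]], edges[k, 1])
    }
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen))
      stop_hetdta("multi-fragment SMILES rejected (", sum(!seen),
                  " disconnected atom(s)): ", smiles)
  }

  degree <- tabulate(c(edges), nbins = n)
  bond_sum <- numeric(n)
  for (k in seq_len(nrow(edges))) {
    bond_sum[edges[k, 1]] <- bond_sum[edges[k, 1]] + orders[k]
    bond_sum[edges[k, 2]] <- bond_sum[edges[k, 2]] + orders[k]
  }
  aromatic <- logical(n)
  rng <- tryCatch(ChemmineR::rings(mol, type = "all", arom = TRUE),
                  error = function(e) NULL)
  if (!is.null(rng) && length(rng$RINGS)) {
    for (r in seq_along(rng$RINGS)) if (isTRUE(rng$AROMATIC[r])) {
      idx <- as.integer(sub("^.*_", "", rng$RINGS[[r]]))
      aromatic[idx] <- TRUE
    }
  }

  feats <- t(vapply(seq_len(n), function(i) {
    sym <- if (symbols[i] %in% ATOM_SYMBOLS) symbols[i] else "Unknown"
    val <- STANDARD_VALENCE[symbols[i]]
    imp <- if (is.na(val)) 0 else max(0, val - bond_sum[i])
    c(one_hot(sym, ATOM_SYMBOLS),
      count_one_hot(degree[i]),
      count_one_hot(as.integer(round(imp))),
      count_one_hot(as.integer(round(imp))),
      as.numeric(aromatic[i]))
  }, numeric(78)))
  new_molecular_graph(feats, edges, "drug")
}

residue_features <- function(sequence) {
  ch <- strsplit(toupper(sequence), "")[[1]]
  ch[!ch %in% AA_ALPHABET] <- "X"
  L <- length(ch)
  t(vapply(seq_len(L), function(i) {
    c(one_hot(ch[i], AA_ALPHABET),
      vapply(AA_PROPERTY_SETS, function(s) as.numeric(ch[i] %in% s), numeric(1)),
      i / L)
  }, numeric(29)))
}

#' Build a protein residue graph from a contact map
#'
#' Residues become nodes; an undirected edge joins residues `i < j` whenever
#' `contact_map[i, j] >= threshold`. Node features (29-dim): residue one-hot
#' over the 20 amino acids plus X, seven physicochemical class flags
#' (aliphatic, aromatic, polar, positively/negatively charged, hydrophobic,
#' small), and the normalised chain position.
#'
#' @param sequence amino-acid string.
#' @param contact_map square matrix with side `nchar(sequence)`, entries in
#'   `[0, 1]` (contact probabilities or a 0/1 map).
#' @param threshold contact probability cut-off, default 0.5.
#' @return a `molecular_graph` of kind `"protein"`.
#' @export
contact_map_to_graph <- function(sequence, contact_map, threshold = 0.5) {
  L <- nchar(sequence)
  if (is.null(contact_map)) stop_hetdta("contact map is missing")
  if (!is.matrix(contact_map) || nrow(contact_map) != L || ncol(contact_map) != L)
    stop_hetdta("contact map must be ", L, "x", L, " for this sequence")
  idx <- which(upper.tri(contact_map) & contact_map >= threshold, arr.ind = TRUE)
  edges <- if (nrow(idx)) cbind(idx[, 1], idx[, 2]) else matrix(integer(0), 0, 2)
  new_molecular_graph(residue_features(sequence), edges, "protein")
}

#' Sequence-window fallback residue graph
#'
#' When no contact map is available, connects every residue pair with
#' `|i - j| <= window`; `window = 1` gives the backbone chain.
#'
#' @param sequence amino-acid string.
#' @param window maximum sequence separation joined by an edge.
#' @return a `molecular_graph` of kind `"protein"`.
#' @export
sequence_to_graph <- function(sequence, window = 1L) {
  L <- nchar(sequence)
  if (L < 1L) stop_hetdta("empty sequence")
  pairs <- which(outer(seq_len(L), seq_len(L), function(i, j) j > i & j - i <= window),
                 arr.ind = TRUE)
  edges <- if (nrow(pairs)) cbind(pairs[, 1], pairs[, 2]) else matrix(integer(0), 0, 2)
  new_molecular_graph(residue_features(sequence), edges, "protein")
}

# residue graph for a protein row: contact map if present, else fallback
protein_graph <- function(sequence, contact_map = NULL, threshold = 0.5, window = 3L) {
  if (!is.null(contact_map)) contact_map_to_graph(sequence, contact_map, threshold)
  else sequence_to_graph(sequence, window)
}
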