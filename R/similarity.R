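# Drug-drug and protein-protein similarity: circular fingerprints + Tanimoto,
# Needleman-Wunsch global alignment (simple scoring and BLOSUM62 affine).

# parse a SMILES once through OpenBabel; errors on invalid input
parse_smiles <- function(smiles) {
  sdf <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(smiles)),
                  error = function(e) stop_hetdta("invalid SMILES: ", smiles))
  mol <- sdf[[1]]
  if (nrow(ChemmineR::atomblock(mol)) < 1L)
    stop_hetdta("SMILES has no heavy atom: ", smiles)
  mol
}

#' Morgan (ECFP) fingerprint of a molecule
#'
#' Circular substructure fingerprint computed by OpenBabel (ECFP family) and
#' folded by bitwise OR down to `n_bits`. `radius` is the circular radius in
#' bonds; ECFP names count the diameter, so `radius = 2` is ECFP4.
#'
#' @param smiles a single SMILES string.
#' @param radius circular radius (0 to 5); default 2 (ECFP4).
#' @param n_bits folded fingerprint length; must divide 4096. Default 1024.
#' @return integer 0/1 vector of length `n_bits` with attributes `radius`
#'   and `n_bits`.
#' @export
morgan_fingerprint <- function(smiles, radius = 2L, n_bits = 1024L) {
  if (!radius %in% 0:5) stop_hetdta("radius must be in 0..5")
  if (4096L %% n_bits != 0L) stop_hetdta("n_bits must divide 4096")
  parse_smiles(smiles)  # validity gate with a clear error
  name <- paste0("ECFP", 2L * radius)
  raw <- ChemmineOB::forEachMol("SMILES", smiles, function(mol)
    ChemmineOB::fingerprint_OB(list(mol), name))[[1]]
  folded <- as.integer(rowSums(matrix(raw, nrow = n_bits)) > 0)
  structure(folded, radius = radius, n_bits = n_bits)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|a AND b| / (|a| + |b| - |a AND b|)` for 0/1 vectors, the binary form of
#' the fingerprint-similarity coefficient. Two all-zero fingerprints are
#' defined to have similarity 0 (with a warning) to avoid 0/0.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop_hetdta("fingerprints must have equal length")
  inter <- sum(a & b)
  denom <- sum(a != 0) + sum(b != 0) - inter
  if (denom == 0) {
    warning("both fingerprints are all-zero; defining similarity as 0")
    return(0)
  }
  inter / denom
}

#' Drug-drug Tanimoto similarity matrix
#'
#' @param drugs data.frame with columns `id` and `smiles`.
#' @param radius,n_bits fingerprint parameters, see [morgan_fingerprint()].
#' @return a `similarity_matrix`: square symmetric matrix in `[0, 1]` with
#'   unit diagonal, dimnames = drug ids, attribute `kind = "drug"`.
#' @export
drug_similarity_matrix <- function(drugs, radius = 2L, n_bits = 1024L) {
  stopifnot(nrow(drugs) >= 1L)
  fps <- lapply(seq_len(nrow(drugs)), function(i)
    tryCatch(morgan_fingerprint(drugs$smiles[i], radius, n_bits),
             error = function(e) stop_hetdta("drug ", drugs$id[i], ": ",
                                             conditionMessage(e))))
  F <- do.call(rbind, fps)
  inter <- F %*% t(F)
  pop <- rowSums(F)
  denom <- outer(pop, pop, "+") - inter
  S <- ifelse(denom == 0, 0, inter / denom)
  diag(S) <- 1
  S <- (S + t(S)) / 2
  dimnames(S) <- list(drugs$id, drugs$id)
  structure(S, kind = "drug", class = c("similarity_matrix", "matrix", "array"))
}

#' Needleman-Wunsch global alignment score (simple scoring)
#'
#' Classic dynamic-programming global alignment with per-position match /
#' mismatch scores and a linear gap penalty. Accepts arbitrary alphabets;
#' empty sequences take the all-gap path.
#'
#' @param seq_a,seq_b character strings.
#' @param match,mismatch,gap scores (gap is the per-symbol penalty, usually
#'   negative).
#' @return optimal global alignment score.
#' @export
nw_score <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -1) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  n <- length(a); m <- length(b)
  prev <- gap * (0:m)
  if (n == 0L) return(prev[m + 1L])
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1L] <- gap * i
    if (m > 0L) {
      sub <- ifelse(b == a[i], match, mismatch)
      for (j in seq_len(m))
        cur[j + 1L] <- max(prev[j] + sub[j], prev[j + 1L] + gap, cur[j] + gap)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Needleman-Wunsch score under a substitution matrix with affine gaps
#'
#' Global alignment score under a named substitution matrix (default
#' BLOSUM62) with affine gap penalties, computed by
#' `Biostrings::pairwiseAlignment`. Residues outside the matrix alphabet are
#' mapped to `X`.
#'
#' @param seq_a,seq_b non-empty amino-acid strings.
#' @param matrix_name substitution matrix name (`"BLOSUM62"`, `"BLOSUM50"`,
#'   `"PAM250"`, ...).
#' @param gap_open,gap_extend positive penalties for opening/extending a gap.
#' @return optimal global alignment score.
#' @export
nw_score_blosum <- function(seq_a, seq_b, matrix_name = "BLOSUM62",
                            gap_open = 10, gap_extend = 1) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop_hetdta("substitution-matrix alignment requires non-empty sequences")
  sm <- get_subst_matrix(matrix_name)
  clean <- function(s) {
    ch <- strsplit(toupper(s), "")[[1]]
    ch[!ch %in% rownames(sm)] <- "X"
    if (!"X" %in% rownames(sm) && any(!ch %in% rownames(sm)))
      stop_hetdta("matrix ", matrix_name, " lacks an X row for unknown residues")
    paste(ch, collapse = "")
  }
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(clean(seq_a)), Biostrings::AAString(clean(seq_b)),
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global", scoreOnly = TRUE)
}

get_subst_matrix <- function(matrix_name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e2) FALSE)
  if (!ok || !exists(matrix_name, envir = e))
    stop_hetdta("unknown substitution matrix: ", matrix_name)
  get(matrix_name, envir = e)
}

#' Protein-protein similarity matrix from global alignment
#'
#' Pairwise global-alignment scores normalised into `[0, 1]` by the
#' geometric mean of the self-alignment scores,
#' `S(a, b) = nw(a, b) / sqrt(nw(a, a) * nw(b, b))`, with negative values
#' clipped to 0 and a unit diagonal.
#'
#' @param proteins data.frame with columns `id` and `sequence`.
#' @param scoring `"blosum"` (default; see [nw_score_blosum()]) or
#'   `"simple"` (see [nw_score()]).
#' @param ... passed to the chosen scorer.
#' @return a `similarity_matrix` with attribute `kind = "protein"`.
#' @export
protein_similarity_matrix <- function(proteins, scoring = c("blosum", "simple"), ...) {
  scoring <- match.arg(scoring)
  stopifnot(nrow(proteins) >= 1L)
  n <- nrow(proteins)
  score <- function(x, y) {
    tryCatch(
      if (scoring == "blosum") nw_score_blosum(x, y, ...) else nw_score(x, y, ...),
      error = function(e) stop_hetdta("alignment failed: ", conditionMessage(e)))
  }
  self <- vapply(proteins$sequence, function(s) score(s, s), numeric(1))
  if (any(self <= 0))
    stop_hetdta("non-positive self-alignment score for protein(s): ",
                paste(proteins$id[self <= 0], collapse = ", "))
  S <- diag(1, n)
  if (n > 1L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- score(proteins$sequence[i], proteins$sequence[j]) / sqrt(self[i] * self[j])
    S[i, j] <- S[j, i] <- max(0, min(1, v))
  }
  dimnames(S) <- list(proteins$id, proteins$id)
  structure(S, kind = "protein", class = c("similarity_matrix", "matrix", "array"))
}

#' Write / read a similarity matrix as plain text with a sidecar id list
#'
#' @param S a `similarity_matrix`.
#' @param path matrix file; ids go to `<path>.ids`.
#' @return `write_similarity_matrix` returns the path invisibly;
#'   `read_similarity_matrix` returns the `similarity_matrix`.
#' @export
write_similarity_matrix <- function(S, path) {
  utils::write.table(unclass(S), path, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(S), paste0(path, ".ids"))
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @param kind `"drug"` or `"protein"` for the loaded matrix.
#' @export
read_similarity_matrix <- function(path, kind = c("drug", "protein")) {
  kind <- match.arg(kind)
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  ids <- readLines(paste0(path, ".ids"))
  check_square_symmetric(m, "similarity matrix")
  dimnames(m) <- list(ids, ids)
  structure(m, kind = kind, class = c("similarity_matrix", "matrix", "array"))
}
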