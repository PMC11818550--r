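# Self-contained synthetic fixtures: valid drug-like SMILES, random protein
# sequences with banded contact maps, and affinities with planted
# similarity structure, so the whole pipeline runs without external data.

# library of known-valid drug-like and fragment SMILES (common scaffolds)
SMILES_LIBRARY <- c(
  "CC(=O)Oc1ccccc1C(=O)O",        # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   # caffeine
  "CC(=O)Nc1ccc(O)cc1",           # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",   # ibuprofen
  "COc1ccc2cc(ccc2c1)C(C)C(=O)O", # naproxen
  "CN1CCCC1c1cccnc1",             # nicotine
  "NCCc1ccc(O)c(O)c1",            # dopamine
  "NCCc1c[nH]c2ccc(O)cc12",       # serotonin
  "NCCc1c[nH]cn1",                # histamine
  "NCCc1ccc(O)cc1",               # tyramine
  "CC(N)Cc1ccccc1",               # amphetamine
  "CNC(C)C(O)c1ccccc1",           # ephedrine
  "CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1", # ketoprofen
  "Nc1ccc(cc1)S(N)(=O)=O",        # sulfanilamide
  "OC(=O)c1ccccc1O",              # salicylic acid
  "NC(=O)c1ccccc1",               # benzamide
  "O=Cc1ccccc1",                  # benzaldehyde
  "OC(=O)c1ccccc1",               # benzoic acid
  "C=Cc1ccccc1",                  # styrene
  "COc1ccccc1",                   # anisole
  "O=[N+]([O-])c1ccccc1",         # nitrobenzene
  "Clc1ccccc1", "Brc1ccccc1", "Fc1ccccc1",
  "N#Cc1ccccc1",                  # benzonitrile
  "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
  "c1ccncc1", "c1c[nH]cn1", "c1ccc2[nH]ccc2c1",
  "c1ccc2ccccc2c1", "c1ccc2ncccc2c1", "c1ccoc1", "c1ccsc1",
  "C1CCCCC1", "C1CCCC1", "C1CCNCC1", "C1CNCCN1", "C1COCCN1",
  "C1CCOC1", "C1COCCO1",
  "CC(C)=O", "CC(=O)O", "CCO", "OCC(O)CO",
  "NC(N)=O",                      # urea
  "NCC(=O)O", "CC(N)C(=O)O", "OCC(N)C(=O)O",
  "CC(O)C(=O)O",                  # lactic acid
  "OC(=O)CCC(=O)O",               # succinic acid
  "OC(=O)CC(O)(CC(=O)O)C(=O)O",   # citric acid
  "Nc1ncnc2[nH]cnc12",            # adenine
  "O=c1cc[nH]c(=O)[nH]1",         # uracil
  "Cc1c[nH]c(=O)[nH]c1=O",        # thymine
  "Nc1cc[nH]c(=O)n1")             # cytosine

# trivially valid chain/ring variants used once the library is exhausted
generated_smiles <- function(k) {
  chains <- vapply(2:12, function(n) strrep("C", n), character(1))
  rings <- vapply(3:10, function(n) paste0("C1", strrep("C", n - 2), "C1"),
                  character(1))
  pool <- c(chains, rings)
  pool[((seq_len(k) - 1L) %% length(pool)) + 1L]
}

#' Specification of a synthetic dataset
#'
#' Defaults describe the conformance fixture used throughout the package
#' tests: 20 drugs by 30 proteins, sequences of 40-60 residues with a
#' contact band of +/-2 and 5% long-range contacts, affinities planted as a
#' linear function of drug- and protein-similarity to seeded reference
#' molecules with Gaussian noise of SD 0.1, seed 42.
#'
#' @param n_drugs,n_proteins molecule counts (both >= 2).
#' @param seq_len_range `(min, max)` protein sequence length.
#' @param contact_band residues within this sequence separation are contacts.
#' @param long_range_contact_prob probability of a contact beyond the band.
#' @param affinity_rule `"linear_similarity"` (planted signal
#'   `5 * sim_drug + 3 * sim_protein + noise`) or `"random"` (iid
#'   `Normal(5, noise_sd)`).
#' @param noise_sd Gaussian noise SD.
#' @param seed integer seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_drugs = 20L, n_proteins = 30L,
                           seq_len_range = c(40L, 60L), contact_band = 2L,
                           long_range_contact_prob = 0.05,
                           affinity_rule = c("linear_similarity", "random"),
                           noise_sd = 0.1, seed = 42L) {
  affinity_rule <- match.arg(affinity_rule)
  stopifnot(n_drugs >= 2L, n_proteins >= 2L,
            long_range_contact_prob >= 0, long_range_contact_prob <= 1,
            noise_sd >= 0)
  structure(list(n_drugs = as.integer(n_drugs), n_proteins = as.integer(n_proteins),
                 seq_len_range = as.integer(seq_len_range),
                 contact_band = as.integer(contact_band),
                 long_range_contact_prob = long_range_contact_prob,
                 affinity_rule = affinity_rule, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Sample synthetic drugs
#'
#' Draws SMILES without replacement from a packaged library of known-valid
#' drug-like structures, then from generated alkane/ring variants; once both
#' are exhausted duplicates are allowed (with a warning).
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `id`, `smiles`.
#' @export
sample_drugs <- function(spec) {
  set.seed(spec$seed)
  pool <- c(sample(SMILES_LIBRARY), generated_smiles(50L))
  n <- spec$n_drugs
  if (n > length(pool)) {
    warning("drug library exhausted; recycling SMILES with duplicates")
    pool <- rep(pool, length.out = n)
  }
  data.frame(id = sprintf("D%03d", seq_len(n)), smiles = pool[seq_len(n)],
             stringsAsFactors = FALSE)
}

# banded contact map with symmetric long-range contacts
synthetic_contact_map <- function(L, band, p_long) {
  sep <- abs(outer(seq_len(L), seq_len(L), "-"))
  m <- (sep <= band) * 1
  if (p_long > 0 && L > band + 1L) {
    long <- which(upper.tri(m) & sep > band)
    hit <- long[stats::runif(length(long)) < p_long]
    m[hit] <- 1
    m[cbind(col(m)[hit], row(m)[hit])] <- 1
  }
  m
}

#' Sample synthetic proteins
#'
#' Uniform random sequences over the 20 amino acids with lengths in
#' `seq_len_range`; each protein carries a contact map that is 1 within the
#' sequence band and contains symmetric long-range contacts with the stated
#' probability.
#'
#' @param spec a [synthetic_spec()].
#' @return data.frame with columns `id`, `sequence` and list column
#'   `contact_map`.
#' @export
sample_proteins <- function(spec) {
  set.seed(spec$seed + 1L)
  aa <- setdiff(AA_ALPHABET, "X")
  n <- spec$n_proteins
  # sample.int avoids the sample() scalar trap when the range is degenerate
  lens <- spec$seq_len_range[1] - 1L +
    sample.int(spec$seq_len_range[2] - spec$seq_len_range[1] + 1L, n,
               replace = TRUE)
  seqs <- vapply(lens, function(L) paste(sample(aa, L, replace = TRUE),
                                         collapse = ""), character(1))
  maps <- lapply(lens, synthetic_contact_map, band = spec$contact_band,
                 p_long = spec$long_range_contact_prob)
  out <- data.frame(id = sprintf("P%03d", seq_len(n)), sequence = seqs,
                    stringsAsFactors = FALSE)
  out$contact_map <- maps
  out
}

#' Plant affinities with similarity structure
#'
#' Under the `linear_similarity` rule every (drug, protein) pair receives
#' `y = 5 * tanimoto(drug, drug_ref) + 3 * nwsim(protein, protein_ref) +
#' Normal(0, noise_sd)`, where the reference molecules are drawn by seed and
#' `nwsim` is the self-score-normalised global-alignment similarity — the
#' same quantities the model's heterogeneous graph is built from, so the
#' fixture carries signal the model can learn. The `random` rule draws iid
#' `Normal(5, noise_sd)` values with no structure.
#'
#' @param drugs,proteins as returned by [sample_drugs()] / [sample_proteins()].
#' @param spec a [synthetic_spec()].
#' @param Sd,Sp optional precomputed similarity matrices (recomputed if
#'   omitted).
#' @return an `affinity_table` over the full cross product, with attributes
#'   `drug_ref` and `protein_ref`.
#' @export
plant_affinities <- function(drugs, proteins, spec, Sd = NULL, Sp = NULL) {
  set.seed(spec$seed + 2L)
  grid <- expand.grid(drug_id = drugs$id, protein_id = proteins$id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (spec$affinity_rule == "random") {
    grid$value <- stats::rnorm(nrow(grid), mean = 5, sd = spec$noise_sd)
    tab <- affinity_table(grid, task = "regression")
    return(tab)
  }
  if (is.null(Sd)) Sd <- drug_similarity_matrix(drugs)
  if (is.null(Sp)) Sp <- protein_similarity_matrix(proteins)
  ref_d <- sample(drugs$id, 1L)
  ref_p <- sample(proteins$id, 1L)
  grid$value <- 5 * Sd[ref_d, grid$drug_id] + 3 * Sp[ref_p, grid$protein_id] +
    stats::rnorm(nrow(grid), sd = spec$noise_sd)
  tab <- affinity_table(grid, task = "regression")
  attr(tab, "drug_ref") <- ref_d
  attr(tab, "protein_ref") <- ref_p
  tab
}

#' Generate a complete synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @return list with `drugs`, `proteins`, `affinities`, `Sd`, `Sp`, `spec`.
#' @export
synthetic_dataset <- function(spec = synthetic_spec()) {
  drugs <- sample_drugs(spec)
  proteins <- sample_proteins(spec)
  Sd <- drug_similarity_matrix(drugs)
  Sp <- protein_similarity_matrix(proteins)
  affinities <- plant_affinities(drugs, proteins, spec, Sd, Sp)
  list(drugs = drugs, proteins = proteins, affinities = affinities,
       Sd = Sd, Sp = Sp, spec = spec)
}
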