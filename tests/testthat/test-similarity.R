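test_that("fingerprints are deterministic, molecule-specific and non-empty", {
  f1 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  f2 <- morgan_fingerprint("CC(=O)Oc1ccccc1C(=O)O")
  expect_identical(f1, f2)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_length(as.integer(f1), 1024L)
  expect_gt(sum(morgan_fingerprint("c1ccccc1")), 0)
  expect_false(identical(as.integer(morgan_fingerprint("C")),
                         as.integer(morgan_fingerprint("CC"))))
  expect_error(morgan_fingerprint("xx(("), "invalid SMILES")
})

test_that("tanimoto matches set arithmetic and handles degenerate input", {
  a <- integer(8); a[c(1, 2, 3)] <- 1L
  b <- integer(8); b[c(2, 3, 4)] <- 1L
  expect_equal(tanimoto(a, b), 0.5)  # |{2,3}| / |{1,2,3,4}|
  expect_equal(tanimoto(a, a), 1)
  d <- integer(8); d[c(5, 6)] <- 1L
  expect_equal(tanimoto(a, d), 0)
  expect_warning(z <- tanimoto(integer(8), integer(8)), "all-zero")
  expect_equal(z, 0)
  expect_error(tanimoto(a, integer(4)), "equal length")
})

test_that("tanimoto symmetry, range and set-oracle agreement on random pairs", {
  set.seed(1)
  for (i in 1:1000) {
    a <- as.integer(stats::runif(32) < 0.3)
    b <- as.integer(stats::runif(32) < 0.3)
    if (sum(a) + sum(b) == 0) next
    t1 <- tanimoto(a, b)
    sa <- which(a == 1); sb <- which(b == 1)
    expect_identical(t1, length(intersect(sa, sb)) / length(union(sa, sb)))
    expect_identical(t1, tanimoto(b, a))
    expect_true(t1 >= 0 && t1 <= 1)
  }
})

test_that("simple-scoring global alignment matches closed forms", {
  expect_equal(nw_score("GATTACA", "GCATGCU", 1, -1, -1), 0)
  expect_equal(nw_score("ACGT", "ACGT", match = 1), 4)
  expect_equal(nw_score("", "AAAA", gap = -1), -4)
  expect_equal(nw_score("AAAA", "", gap = -2), -8)
})

test_that("alignment DP equals exhaustive enumeration for short sequences", {
  set.seed(7)
  for (i in 1:60) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(1:6, 1), replace = TRUE), collapse = "")
    sc <- c(match = sample(1:3, 1), mismatch = -sample(1:3, 1), gap = -sample(1:3, 1))
    expect_equal(nw_score(a, b, sc["match"], sc["mismatch"], sc["gap"]),
                 nw_enumerate(a, b, sc["match"], sc["mismatch"], sc["gap"]),
                 info = paste(a, b, paste(sc, collapse = "/")))
  }
})

test_that("substitution-matrix alignment agrees with linear-gap DP as a cross-check", {
  # with gap open 0 the affine scheme reduces to a linear gap penalty,
  # making the independent simple DP comparable under a +1/-1 matrix
  set.seed(3)
  sm <- matrix(-1, 20, 20, dimnames = list(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                           strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  diag(sm) <- 1
  for (i in 1:10) {
    a <- random_aa(sample(3:8, 1)); b <- random_aa(sample(3:8, 1))
    got <- Biostrings::pairwiseAlignment(Biostrings::AAString(a), Biostrings::AAString(b),
                                         substitutionMatrix = sm, gapOpening = 0,
                                         gapExtension = 1, type = "global",
                                         scoreOnly = TRUE)
    expect_equal(nw_score(a, b, 1, -1, -1), got)
  }
  expect_equal(nw_score_blosum("MKT", "MKT"),
               Biostrings::pairwiseAlignment(Biostrings::AAString("MKT"),
                                             Biostrings::AAString("MKT"),
                                             substitutionMatrix = "BLOSUM62",
                                             gapOpening = 10, gapExtension = 1,
                                             type = "global", scoreOnly = TRUE))
  expect_error(nw_score_blosum("", "MKT"), "non-empty")
  expect_error(nw_score_blosum("MKT", "MKT", matrix_name = "NOPE"), "unknown")
})

test_that("drug similarity matrices satisfy their invariants and the pairwise oracle", {
  one <- drug_similarity_matrix(data.frame(id = "d", smiles = "CCO"))
  expect_equal(unclass(one), matrix(1, 1, 1, dimnames = list("d", "d")),
               ignore_attr = "kind")
  dup <- drug_similarity_matrix(data.frame(id = c("a", "b"),
                                           smiles = c("c1ccccc1", "c1ccccc1")))
  expect_equal(dup["a", "b"], 1)
  drugs <- data.frame(id = c("x", "y", "z"),
                      smiles = c("CC(=O)Oc1ccccc1C(=O)O", "CCO", "Cn1cnc2c1c(=O)n(C)c(=O)n2C"))
  S <- drug_similarity_matrix(drugs)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(S[i, j],
                 tanimoto(morgan_fingerprint(drugs$smiles[i]),
                          morgan_fingerprint(drugs$smiles[j])))
  }
  expect_identical(unclass(S), t(unclass(S)))
  expect_equal(unname(diag(S)), rep(1, 3))
  expect_error(drug_similarity_matrix(data.frame(id = "bad", smiles = "((")), "bad")
})

test_that("protein similarity is self-score-normalised into [0,1] with unit diagonal", {
  same <- protein_similarity_matrix(data.frame(id = c("a", "b"),
                                               sequence = c("MKTAYIAK", "MKTAYIAK")))
  expect_equal(same["a", "b"], 1)
  one <- protein_similarity_matrix(data.frame(id = "p", sequence = "MKWV"))
  expect_equal(unclass(one), matrix(1, 1, 1, dimnames = list("p", "p")),
               ignore_attr = "kind")
  set.seed(5)
  prots <- data.frame(id = c("p1", "p2", "p3"),
                      sequence = vapply(c(12, 15, 10), random_aa, character(1)))
  S <- protein_similarity_matrix(prots)
  self <- vapply(prots$sequence, function(s) nw_score_blosum(s, s), numeric(1))
  for (i in 1:2) for (j in (i + 1):3) {
    raw <- nw_score_blosum(prots$sequence[i], prots$sequence[j]) /
      sqrt(self[i] * self[j])
    expect_equal(S[i, j], max(0, min(1, raw)))
  }
  expect_true(all(S >= 0 & S <= 1))
  expect_identical(unclass(S), t(unclass(S)))
})

test_that("similarity matrices round-trip through their text format", {
  ds <- small_dataset()
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sd.txt")
  write_similarity_matrix(ds$Sd, p)
  back <- read_similarity_matrix(p, "drug")
  expect_equal(unclass(back), unclass(ds$Sd), tolerance = 1e-12)
  expect_identical(rownames(back), rownames(ds$Sd))
})
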