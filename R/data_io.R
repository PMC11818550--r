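#' Read a drug or protein table
#'
#' Accepts either a two-column TSV (`id<TAB>string`, no header) or a JSON
#' dictionary mapping id to string, the layout the DeepDTA-family benchmark
#' archives use for `ligands_can.txt` / `proteins.txt`.
#'
#' @param path file path.
#' @param what `"smiles"` or `"sequence"`; names the value column.
#' @return a data.frame with columns `id` and either `smiles` or `sequence`.
#' @export
read_entity_table <- function(path, what = c("smiles", "sequence")) {
  what <- match.arg(what)
  if (!file.exists(path)) stop_hetdta("file not found: ", path)
  first <- readChar(path, nchars = 1L, useBytes = TRUE)
  if (identical(first, "{")) {
    d <- jsonlite::fromJSON(path)
    df <- data.frame(id = names(d), value = unname(unlist(d)),
                     stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character")
    if (ncol(df) != 2L) stop_hetdta(path, ": expected two tab-separated columns")
    names(df) <- c("id", "value")
  }
  if (anyDuplicated(df$id))
    stop_hetdta(path, ": duplicated ids: ",
                paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  names(df)[2] <- what
  df
}

#' Read an affinity table
#'
#' Three-column TSV (`drug_id<TAB>protein_id<TAB>value`, no header).
#'
#' @param path file path.
#' @param task `"regression"` or `"classification"`.
#' @return an `affinity_table`: data.frame with columns `drug_id`,
#'   `protein_id`, `value` plus attributes `task` and `n`.
#' @export
read_affinity_table <- function(path, task = c("regression", "classification")) {
  task <- match.arg(task)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 3L) stop_hetdta(path, ": expected three tab-separated columns")
  names(df) <- c("drug_id", "protein_id", "value")
  affinity_table(df, task = task)
}

#' Construct an affinity table
#'
#' @param records data.frame with columns `drug_id`, `protein_id`, `value`.
#' @param task `"regression"` or `"classification"`.
#' @return the validated `affinity_table`.
#' @export
affinity_table <- function(records, task = c("regression", "classification")) {
  task <- match.arg(task)
  stopifnot(all(c("drug_id", "protein_id", "value") %in% names(records)))
  records$drug_id <- as.character(records$drug_id)
  records$protein_id <- as.character(records$protein_id)
  records$value <- as.numeric(records$value)
  key <- paste(records$drug_id, records$protein_id, sep = "\r")
  if (anyDuplicated(key))
    stop_hetdta("duplicated (drug_id, protein_id) pairs: ",
                paste(utils::head(sub("\r", "/", key[duplicated(key)]), 5), collapse = ", "))
  if (task == "classification" && !all(records$value %in% c(0, 1)))
    stop_hetdta("classification values must be 0/1")
  if (anyNA(records$value)) stop_hetdta("affinity values contain NA")
  structure(records[, c("drug_id", "protein_id", "value")],
            task = task, n = nrow(records),
            class = c("affinity_table", "data.frame"))
}

#' Load a full dataset (drugs, proteins, affinities, optional contact maps)
#'
#' @param drug_path two-column TSV or JSON dict of id to SMILES.
#' @param protein_path two-column TSV or JSON dict of id to sequence.
#' @param affinity_path three-column TSV of (drug_id, protein_id, value).
#' @param task `"regression"` or `"classification"`.
#' @param contact_dir optional directory holding per-protein contact maps as
#'   whitespace-delimited square text matrices named `<protein_id>.txt`.
#' @param validate_smiles parse every SMILES and fail loudly on invalid rows.
#' @return a list with `drugs`, `proteins` (data.frames; proteins carry a
#'   `contact_map` list column when maps are supplied) and `affinities`.
#' @export
load_dataset <- function(drug_path, protein_path, affinity_path,
                         task = c("regression", "classification"),
                         contact_dir = NULL, validate_smiles = TRUE) {
  task <- match.arg(task)
  drugs <- read_entity_table(drug_path, "smiles")
  proteins <- read_entity_table(protein_path, "sequence")
  aff <- read_affinity_table(affinity_path, task)

  bad_d <- setdiff(aff$drug_id, drugs$id)
  if (length(bad_d))
    stop_hetdta("affinity rows reference unknown drug id(s): ",
                paste(bad_d, collapse = ", "))
  bad_p <- setdiff(aff$protein_id, proteins$id)
  if (length(bad_p))
    stop_hetdta("affinity rows reference unknown protein id(s): ",
                paste(bad_p, collapse = ", "))

  if (validate_smiles) {
    ok <- vapply(drugs$smiles, function(s)
      !inherits(try(parse_smiles(s), silent = TRUE), "try-error"), logical(1))
    if (!all(ok))
      stop_hetdta("unparseable SMILES for drug id(s): ",
                  paste(drugs$id[!ok], collapse = ", "))
  }

  if (!is.null(contact_dir)) {
    proteins$contact_map <- lapply(seq_len(nrow(proteins)), function(i) {
      f <- file.path(contact_dir, paste0(proteins$id[i], ".txt"))
      if (!file.exists(f)) return(NULL)
      read_contact_map(f, nchar(proteins$sequence[i]))
    })
  }
  message(sprintf("loaded %d drugs, %d proteins, %d affinity records",
                  nrow(drugs), nrow(proteins), nrow(aff)))
  list(drugs = drugs, proteins = proteins, affinities = aff)
}

#' Read a contact map
#'
#' Whitespace-delimited square numeric text matrix; validated to be square,
#' symmetric, with entries in `[0, 1]`, and (when `expected_side` is given)
#' of side equal to the protein's sequence length.
#'
#' @param path file path.
#' @param expected_side optional required side length.
#' @return a numeric matrix.
#' @export
read_contact_map <- function(path, expected_side = NULL) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (!is.null(expected_side) && nrow(m) != expected_side)
    stop_hetdta(path, ": contact map side ", nrow(m),
                " != sequence length ", expected_side)
  check_square_symmetric(m, paste0("contact map ", path))
  m
}

#' Write a dataset in the layout `load_dataset()` reads
#'
#' @param dataset list with `drugs`, `proteins`, `affinities` as returned by
#'   [load_dataset()] or [synthetic_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dp <- file.path(dir, "drugs.tsv")
  pp <- file.path(dir, "proteins.tsv")
  ap <- file.path(dir, "affinities.tsv")
  utils::write.table(dataset$drugs[, c("id", "smiles")], dp, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$proteins[, c("id", "sequence")], pp, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$affinities, ap, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  cm_dir <- NULL
  if (!is.null(dataset$proteins$contact_map)) {
    cm_dir <- file.path(dir, "contact_maps")
    dir.create(cm_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(dataset$proteins))) {
      m <- dataset$proteins$contact_map[[i]]
      if (is.null(m)) next
      utils::write.table(m, file.path(cm_dir, paste0(dataset$proteins$id[i], ".txt")),
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(list(drugs = dp, proteins = pp, affinities = ap, contact_dir = cm_dir))
}

#' Transform affinity values
#'
#' `neg_log10_nM` converts dissociation constants in nanomolar to the pKd
#' scale: `-log10(Kd * 1e-9)`, the convention for Davis-style data. `none`
#' is the identity (KIBA scores are used as-is).
#'
#' @param values numeric vector.
#' @param mode `"none"` or `"neg_log10_nM"`.
#' @return transformed numeric vector.
#' @export
transform_affinity <- function(values, mode = c("none", "neg_log10_nM")) {
  mode <- match.arg(mode)
  if (mode == "none") return(values)
  if (any(values <= 0))
    stop_hetdta("neg_log10_nM requires strictly positive Kd values")
  -log10(values * 1e-9)
}

#' Train/test and fivefold cross-validation split plan
#'
#' Holds out `floor(n/6)` records as the test set (a 5:1 train:test ratio)
#' and partitions the remaining records into five validation folds, all by a
#' seeded shuffle.
#'
#' @param table an `affinity_table` (or anything with `nrow`).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @return a `split_plan`: list with `test_indices`, `folds` (five
#'   `(train, validation)` index pairs over non-test records), `n`, `seed`.
#' @export
make_splits <- function(table, seed = 1L) {
  n <- nrow(table)
  if (n < 6L) stop_hetdta("need at least 6 records to split 5:1")
  old <- .Random.seed_exists()
  set.seed(seed)
  perm <- sample.int(n)
  n_test <- floor(n / 6)
  test_idx <- sort(perm[seq_len(n_test)])
  rest <- perm[(n_test + 1L):n]
  fold_id <- rep(1:5, length.out = length(rest))  # sizes differ by at most 1
  folds <- lapply(1:5, function(k) {
    val <- sort(rest[fold_id == k])
    list(train = sort(rest[fold_id != k]), validation = val)
  })
  on.exit(.restore_seed(old))
  structure(list(test_indices = test_idx, folds = folds, n = n, seed = seed),
            class = "split_plan")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: n=%d, test=%d, five folds of sizes %s (seed %d)\n",
              x$n, length(x$test_indices),
              paste(vapply(x$folds, function(f) length(f$validation), integer(1)),
                    collapse = "/"), x$seed))
  invisible(x)
}
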