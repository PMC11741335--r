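# Dataset container: one tibble row per molecule, list-columns for the
# per-atom and per-frame arrays, plus dataset-level scalars.

SPLIT_LEVELS <- c("train", "validate", "test")

#' Construct a fine-tuning dataset
#'
#' A `ct_dataset` bundles, per molecule: the atom embedding matrix
#' (`n_atoms x m`), foundation electronegativities `e` (kcal mol^-1 e^-1),
#' hardnesses `s` (kcal mol^-1 e^-2, strictly positive), partial charges
#' `q` (e), total charge `Q` (e), baseline calculated and experimental
#' free energies with uncertainties (kcal/mol), and a `n_frames x n_atoms`
#' matrix `phi` of per-atom environment electrostatic potentials
#' (kcal mol^-1 e^-1) saved from equilibrium sampling at the unperturbed
#' potential. `beta` is the inverse thermal energy of the bath.
#'
#' @param molecules A data frame with columns `molecule_id`, `n_atoms`,
#'   `Q`, `dG_calc`, `dG_calc_unc`, `dG_expt`, `dG_expt_unc`, `split`, and
#'   list-columns `embeddings`, `e`, `s`, `q`, `phi` (and optionally
#'   `spec` and `q_true` for synthetic datasets carrying generator
#'   oracles).
#' @param beta Inverse thermal energy, mol kcal^-1 (default 298.15 K).
#' @param m Embedding dimension; inferred from the first molecule when
#'   `NULL`.
#' @param metadata Named list of provenance (seed, generator parameters,
#'   temperature, ...).
#' @param validate Run [validate_dataset()] (default `TRUE`).
#' @return An object of class `ct_dataset`.
#' @seealso [validate_dataset()], [assign_splits()], [write_dataset()]
#' @export
ct_dataset <- function(molecules, beta = default_beta(), m = NULL,
                       metadata = list(), validate = TRUE) {
  molecules <- as_tibble(molecules)
  if (is.null(m)) {
    if (nrow(molecules) == 0L) abort("cannot infer `m` from an empty dataset")
    m <- ncol(molecules$embeddings[[1L]])
  }
  x <- structure(
    list(molecules = molecules, beta = beta, m = as.integer(m),
         metadata = metadata),
    class = "ct_dataset"
  )
  if (validate) validate_dataset(x)
  x
}

#' @export
print.ct_dataset <- function(x, ...) {
  n <- nrow(x$molecules)
  cat(sprintf(
    "<ct_dataset> %d molecules, m = %d, beta = %.4f mol/kcal\n",
    n, x$m, x$beta))
  if (n > 0) {
    cat("  splits:",
        paste(sprintf("%s=%d", SPLIT_LEVELS,
                      vapply_dbl(SPLIT_LEVELS,
                                 function(s) sum(x$molecules$split == s))),
              collapse = ", "), "\n")
    cat(sprintf("  frames: %s per molecule\n",
                paste(range(vapply_dbl(x$molecules$phi, nrow)),
                      collapse = "-")))
  }
  invisible(x)
}

#' Number of molecules in a dataset
#' @param x A `ct_dataset`.
#' @export
n_molecules <- function(x) nrow(x$molecules)

#' Validate dataset invariants
#'
#' Checks every molecule record: hardness strictly positive, charges
#' summing to the total molecular charge within 1e-8 e, `phi` with at
#' least two frames and exactly `n_atoms` columns, embeddings with
#' exactly `m` columns shared across the dataset, unique molecule ids,
#' and `beta > 0`. Violations raise an error naming the molecule and the
#' offending field.
#'
#' @param dataset A `ct_dataset`.
#' @param check_qeq Also diagnose whether stored charges are consistent
#'   with QEq applied to `(e, s, Q)`; inconsistencies beyond 1e-6 e emit
#'   a warning with the largest deviation (they break the exact
#'   zero-perturbation identity).
#' @return The dataset, invisibly.
#' @export
validate_dataset <- function(dataset, check_qeq = FALSE) {
  stopifnot(inherits(dataset, "ct_dataset"))
  mol <- dataset$molecules
  need <- c("molecule_id", "n_atoms", "Q", "dG_calc", "dG_calc_unc",
            "dG_expt", "dG_expt_unc", "split", "embeddings", "e", "s",
            "q", "phi")
  missing_cols <- setdiff(need, names(mol))
  if (length(missing_cols) > 0) {
    abort(paste0("dataset is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(mol$molecule_id)) {
    abort("molecule_id values must be unique")
  }
  if (!is.numeric(dataset$beta) || length(dataset$beta) != 1L ||
      !is.finite(dataset$beta) || dataset$beta <= 0) {
    abort("`beta` must be a positive finite scalar")
  }
  bad_split <- setdiff(unique(mol$split), SPLIT_LEVELS)
  if (length(bad_split) > 0) {
    abort(paste0("unknown split label(s): ", paste(bad_split, collapse = ", ")))
  }
  fail <- function(id, field, msg) {
    abort(sprintf("molecule \"%s\": invalid `%s` (%s)", id, field, msg))
  }
  for (i in seq_len(nrow(mol))) {
    id <- mol$molecule_id[[i]]
    n <- mol$n_atoms[[i]]
    emb <- mol$embeddings[[i]]
    e <- mol$e[[i]]; s <- mol$s[[i]]; q <- mol$q[[i]]
    phi <- mol$phi[[i]]
    if (!is.matrix(emb) || nrow(emb) != n) {
      fail(id, "embeddings", sprintf("expected %d rows", n))
    }
    if (ncol(emb) != dataset$m) {
      fail(id, "embeddings",
           sprintf("%d columns but dataset m = %d", ncol(emb), dataset$m))
    }
    if (length(e) != n || !all(is.finite(e))) fail(id, "e", "length/finiteness")
    if (length(s) != n || !all(is.finite(s))) fail(id, "s", "length/finiteness")
    if (any(s <= 0)) fail(id, "s", "hardness must be strictly positive")
    if (length(q) != n) fail(id, "q", sprintf("expected length %d", n))
    dq <- abs(sum(q) - mol$Q[[i]])
    if (dq > 1e-8) {
      fail(id, "q", sprintf("sum(q) - Q = %.3g exceeds 1e-8 e", dq))
    }
    if (!is.matrix(phi) || ncol(phi) != n) {
      fail(id, "phi", sprintf("expected %d columns", n))
    }
    if (nrow(phi) < 2L) fail(id, "phi", "needs at least 2 frames")
    if (!all(is.finite(phi))) fail(id, "phi", "non-finite entries")
  }
  if (check_qeq) {
    dev <- vapply_dbl(seq_len(nrow(mol)), function(i) {
      max(abs(qeq_charges(mol$e[[i]], mol$s[[i]], mol$Q[[i]]) - mol$q[[i]]))
    })
    if (any(dev > 1e-6)) {
      worst <- which.max(dev)
      warn(sprintf(
        paste0("stored charges are not QEq-consistent with (e, s, Q); ",
               "max |dq| = %.3g e (molecule \"%s\"). The zero-perturbation ",
               "identity holds only for QEq-consistent charges."),
        dev[worst], mol$molecule_id[[worst]]))
    }
  }
  invisible(dataset)
}

# Extract molecule i (index or id) as a plain record list.
get_record <- function(dataset, i) {
  mol <- dataset$molecules
  if (is.character(i)) {
    j <- match(i, mol$molecule_id)
    if (is.na(j)) abort(sprintf("unknown molecule_id \"%s\"", i))
    i <- j
  }
  list(
    molecule_id = mol$molecule_id[[i]], n_atoms = mol$n_atoms[[i]],
    embeddings = mol$embeddings[[i]], e = mol$e[[i]], s = mol$s[[i]],
    q = mol$q[[i]], Q = mol$Q[[i]], dG_calc = mol$dG_calc[[i]],
    dG_calc_unc = mol$dG_calc_unc[[i]], dG_expt = mol$dG_expt[[i]],
    dG_expt_unc = mol$dG_expt_unc[[i]], phi = mol$phi[[i]],
    split = mol$split[[i]],
    spec = if ("spec" %in% names(mol)) mol$spec[[i]] else NULL,
    q_true = if ("q_true" %in% names(mol)) mol$q_true[[i]] else NULL
  )
}

#' Assign train/validate/test splits
#'
#' Molecules are assigned uniformly at random without replacement:
#' `floor(train_fraction * N)` molecules to train, and the remaining
#' non-training molecules split 25%/75% into validate/test (floor for
#' validate, remainder to test). Deterministic given `seed`; split sizes
#' depend only on `N` and `train_fraction`.
#'
#' @param dataset A `ct_dataset` with at least 4 molecules.
#' @param train_fraction Fraction in (0, 1) of molecules assigned to the
#'   training split.
#' @param seed Integer RNG seed.
#' @return The dataset with the `split` column reassigned.
#' @export
assign_splits <- function(dataset, train_fraction, seed) {
  stopifnot(inherits(dataset, "ct_dataset"))
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    abort("`train_fraction` must lie in (0, 1)")
  }
  n <- n_molecules(dataset)
  if (n < 4L) abort("split assignment needs at least 4 molecules")
  n_train <- floor(train_fraction * n)
  if (n_train < 1L) abort("`train_fraction` produces an empty training set")
  n_val <- floor(0.25 * (n - n_train))
  n_test <- n - n_train - n_val
  perm <- withr::with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(n_train)]] <- "train"
  if (n_val > 0) split[perm[n_train + seq_len(n_val)]] <- "validate"
  if (n_test > 0) split[perm[n_train + n_val + seq_len(n_test)]] <- "test"
  if (n_val == 0L || n_test == 0L) {
    warn(sprintf("empty split produced (train=%d, validate=%d, test=%d)",
                 n_train, n_val, n_test))
  }
  dataset$molecules$split <- split
  dataset$metadata$split <- list(train_fraction = train_fraction, seed = seed)
  dataset
}

#' Per-split molecule counts
#' @param dataset A `ct_dataset`.
#' @return A tibble with columns `split` and `n`.
#' @export
split_sizes <- function(dataset) {
  dataset$molecules |>
    dplyr::count(split = factor(split, levels = SPLIT_LEVELS),
                 .drop = FALSE) |>
    dplyr::mutate(split = as.character(split))
}
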