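# On-disk dataset container: a directory holding a JSON manifest plus
# Arrow parquet tables. Parquet stores IEEE doubles losslessly, so the
# write -> read round trip is exact on every numeric field.

CONTAINER_FORMAT <- "chargetune-dataset"
CONTAINER_VERSION <- 1L

#' Write a dataset container to disk
#'
#' Serializes a [ct_dataset()] as a directory containing `manifest.json`
#' (ids, splits, embedding dimension, metadata) and parquet tables for
#' molecule scalars, per-atom arrays (embeddings, e, s, q), the
#' frames-by-atoms potential matrices, and - for synthetic datasets - the
#' generator's Gaussian ensemble specifications so that closed-form
#' oracles survive a round trip.
#'
#' @param dataset A valid `ct_dataset`.
#' @param path Directory to create (must not exist unless
#'   `overwrite = TRUE`).
#' @param overwrite Replace an existing container.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, overwrite = FALSE) {
  validate_dataset(dataset)
  if (dir.exists(path)) {
    if (!overwrite) abort(sprintf("path already exists: %s", path))
    unlink(path, recursive = TRUE)
  }
  dir.create(path, recursive = TRUE)
  mol <- dataset$molecules

  manifest <- list(
    format = CONTAINER_FORMAT,
    version = CONTAINER_VERSION,
    m = dataset$m,
    molecule_ids = as.list(mol$molecule_id),
    splits = as.list(setNames(mol$split, mol$molecule_id)),
    has_oracle = "spec" %in% names(mol) && !is.null(mol$spec[[1L]]),
    metadata = dataset$metadata
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  arrow::write_parquet(
    tibble(beta = dataset$beta, m = dataset$m),
    file.path(path, "dataset.parquet"))

  arrow::write_parquet(
    tibble(
      molecule_id = mol$molecule_id,
      n_atoms = as.integer(mol$n_atoms),
      n_frames = vapply(mol$phi, nrow, integer(1)),
      Q = mol$Q, dG_calc = mol$dG_calc, dG_calc_unc = mol$dG_calc_unc,
      dG_expt = mol$dG_expt, dG_expt_unc = mol$dG_expt_unc,
      split = mol$split),
    file.path(path, "molecules.parquet"))

  atoms <- purrr::map_dfr(seq_len(nrow(mol)), function(i) {
    emb <- mol$embeddings[[i]]
    colnames(emb) <- sprintf("h_%d", seq_len(ncol(emb)))
    dplyr::bind_cols(
      tibble(molecule_id = mol$molecule_id[[i]],
             atom = seq_len(mol$n_atoms[[i]]),
             e = mol$e[[i]], s = mol$s[[i]], q = mol$q[[i]],
             q_true = if ("q_true" %in% names(mol) &&
                          !is.null(mol$q_true[[i]])) mol$q_true[[i]]
                      else NA_real_),
      as_tibble(emb))
  })
  arrow::write_parquet(atoms, file.path(path, "atoms.parquet"))

  phi_long <- purrr::map_dfr(seq_len(nrow(mol)), function(i) {
    phi <- mol$phi[[i]]
    tibble(
      molecule_id = mol$molecule_id[[i]],
      frame = rep(seq_len(nrow(phi)), times = ncol(phi)),
      atom = rep(seq_len(ncol(phi)), each = nrow(phi)),
      phi = as.vector(phi))
  })
  arrow::write_parquet(phi_long, file.path(path, "phi.parquet"))

  if (isTRUE(manifest$has_oracle)) {
    specs <- mol$spec
    arrow::write_parquet(
      purrr::map_dfr(seq_len(nrow(mol)), function(i) {
        tibble(molecule_id = mol$molecule_id[[i]],
               atom = seq_along(specs[[i]]$mu0),
               mu0 = specs[[i]]$mu0,
               n_frames = specs[[i]]$n_frames,
               seed = specs[[i]]$seed)
      }),
      file.path(path, "oracle_mu0.parquet"))
    arrow::write_parquet(
      purrr::map_dfr(seq_len(nrow(mol)), function(i) {
        n <- length(specs[[i]]$mu0)
        idx <- expand.grid(i_ = seq_len(n), j_ = seq_len(n))
        tibble(molecule_id = mol$molecule_id[[i]],
               row = rep(idx$i_, 2L), col = rep(idx$j_, 2L),
               kind = rep(c("A", "Sigma_phi"), each = n * n),
               value = c(as.vector(specs[[i]]$A),
                         as.vector(specs[[i]]$Sigma_phi)))
      }),
      file.path(path, "oracle_matrices.parquet"))
  }
  invisible(path)
}

#' Read a dataset container from disk
#'
#' Inverse of [write_dataset()]. Fails loudly on schema mismatches:
#' missing tables, an embedding dimension that disagrees with the
#' manifest, or unknown split labels.
#'
#' @param path Directory written by [write_dataset()].
#' @return A validated `ct_dataset`.
#' @export
read_dataset <- function(path) {
  if (!dir.exists(path)) abort(sprintf("no dataset container at: %s", path))
  need <- c("manifest.json", "dataset.parquet", "molecules.parquet",
            "atoms.parquet", "phi.parquet")
  have <- file.exists(file.path(path, need))
  if (!all(have)) {
    abort(sprintf("container is missing: %s",
                  paste(need[!have], collapse = ", ")))
  }
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"))
  if (!identical(manifest$format, CONTAINER_FORMAT)) {
    abort("manifest does not describe a chargetune dataset container")
  }
  m <- as.integer(manifest$m)
  scalars <- as.data.frame(
    arrow::read_parquet(file.path(path, "dataset.parquet")))
  mols <- as.data.frame(
    arrow::read_parquet(file.path(path, "molecules.parquet")))
  atoms <- as.data.frame(
    arrow::read_parquet(file.path(path, "atoms.parquet")))
  phi_long <- as.data.frame(
    arrow::read_parquet(file.path(path, "phi.parquet")))

  h_cols <- sprintf("h_%d", seq_len(m))
  missing_h <- setdiff(h_cols, names(atoms))
  if (length(missing_h) > 0 ||
      length(grep("^h_", names(atoms))) != m) {
    abort(sprintf(
      "embedding columns disagree with manifest m = %d (found %d)",
      m, length(grep("^h_", names(atoms)))))
  }

  ids <- unlist(manifest$molecule_ids)
  atoms_by <- split(atoms, factor(atoms$molecule_id, levels = ids))
  phi_by <- split(phi_long, factor(phi_long$molecule_id, levels = ids))

  has_oracle <- isTRUE(manifest$has_oracle)
  if (has_oracle) {
    mu0_tab <- as.data.frame(
      arrow::read_parquet(file.path(path, "oracle_mu0.parquet")))
    mat_tab <- as.data.frame(
      arrow::read_parquet(file.path(path, "oracle_matrices.parquet")))
    mu0_by <- split(mu0_tab, factor(mu0_tab$molecule_id, levels = ids))
    mat_by <- split(mat_tab, factor(mat_tab$molecule_id, levels = ids))
  }

  rows <- purrr::map(seq_along(ids), function(k) {
    id <- ids[[k]]
    sc <- mols[mols$molecule_id == id, , drop = FALSE]
    if (nrow(sc) != 1L) abort(sprintf("molecule \"%s\" missing from scalars", id))
    at <- atoms_by[[id]]
    at <- at[order(at$atom), , drop = FALSE]
    n <- sc$n_atoms
    ph <- phi_by[[id]]
    if (is.null(ph) || nrow(ph) == 0L) {
      abort(sprintf("molecule \"%s\" missing from phi table", id))
    }
    phi <- matrix(NA_real_, sc$n_frames, n)
    phi[cbind(ph$frame, ph$atom)] <- ph$phi
    rec <- tibble(
      molecule_id = id, n_atoms = as.integer(n),
      Q = sc$Q, dG_calc = sc$dG_calc, dG_calc_unc = sc$dG_calc_unc,
      dG_expt = sc$dG_expt, dG_expt_unc = sc$dG_expt_unc,
      split = manifest$splits[[id]] %||% sc$split,
      embeddings = list(unname(as.matrix(at[, h_cols]))),
      e = list(at$e), s = list(at$s), q = list(at$q),
      phi = list(phi))
    if (!all(is.na(at$q_true))) rec$q_true <- list(at$q_true)
    if (has_oracle) {
      mu <- mu0_by[[id]]; mu <- mu[order(mu$atom), , drop = FALSE]
      mt <- mat_by[[id]]
      to_mat <- function(kind) {
        sub <- mt[mt$kind == kind, , drop = FALSE]
        out <- matrix(NA_real_, n, n)
        out[cbind(sub$row, sub$col)] <- sub$value
        out
      }
      rec$spec <- list(ensemble_spec(
        mu0 = mu$mu0, A = to_mat("A"), Sigma_phi = to_mat("Sigma_phi"),
        n_frames = mu$n_frames[[1L]], seed = mu$seed[[1L]]))
    }
    rec
  })
  molecules <- dplyr::bind_rows(rows)
  if ("q_true" %in% names(molecules)) {
    # bind_rows drops list entries for molecules lacking q_true; normalize
    molecules$q_true <- purrr::map(molecules$q_true, identity)
  }
  ct_dataset(molecules, beta = scalars$beta, m = m,
             metadata = manifest$metadata %||% list())
}
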