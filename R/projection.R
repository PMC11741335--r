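# Principal-component basis over pooled atom embeddings. Eigenvalues
# follow the unnormalized-scatter convention (squared singular values of
# the centered data matrix, no 1/n), and eigenvector signs are fixed
# deterministically so repeated fits are identical.

#' Pool atom embeddings into a data matrix
#'
#' Concatenates every atom's embedding vector as a column of an
#' `m x n_total_atoms` matrix, in molecule order then atom order.
#'
#' @param dataset A `ct_dataset`.
#' @return A numeric matrix with `m` rows.
#' @export
pool_embeddings <- function(dataset) {
  stopifnot(inherits(dataset, "ct_dataset"))
  if (n_molecules(dataset) == 0L) abort("cannot pool an empty dataset")
  dims <- unique(vapply_dbl(dataset$molecules$embeddings, ncol))
  if (length(dims) != 1L) {
    abort("molecules have mixed embedding dimensions")
  }
  do.call(cbind, lapply(dataset$molecules$embeddings, t))
}

new_basis <- function(rotation, mu, variances, center) {
  r <- ncol(rotation)
  gram <- crossprod(rotation)
  if (max(abs(gram - diag(r))) > 1e-8) {
    abort("basis columns are not orthonormal")
  }
  if (is.unsorted(-variances)) abort("variances must be non-increasing")
  structure(
    list(rotation = rotation, mu = mu, variances = variances,
         r = r, center = center),
    class = "ct_basis")
}

#' @export
print.ct_basis <- function(x, ...) {
  cat(sprintf("<ct_basis> m = %d, r = %d, centered projection: %s\n",
              nrow(x$rotation), x$r, x$center))
  cat(sprintf("  explained variance (top): %s\n",
              paste(signif(head(x$variances, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Fit a truncated principal-component basis
#'
#' Finds the `r` orthogonal directions of highest variance in the pooled
#' embeddings: the top-`r` eigenvectors of the centered scatter matrix
#' `(H - mu)(H - mu)^T`, computed through the singular value
#' decomposition of the centered data matrix for numerical stability.
#' `variances` are the corresponding eigenvalues (squared singular
#' values) in descending order. The sign of each eigenvector is fixed by
#' making its largest-magnitude component positive.
#'
#' @param x An `m x n` data matrix with one atom embedding per column, or
#'   a `ct_dataset` (pooled with [pool_embeddings()]).
#' @param r Number of components, `1 <= r <= min(m, n)`.
#' @param center Whether [project()] subtracts the mean embedding before
#'   rotating (default `TRUE`; `FALSE` projects raw vectors).
#' @param ... Passed between methods.
#' @return A `ct_basis` with fields `rotation` (`m x r`, orthonormal
#'   columns), `mu` (mean embedding), `variances`, `r`, `center`.
#' @export
fit_basis <- function(x, r, ...) UseMethod("fit_basis")

#' @rdname fit_basis
#' @export
fit_basis.ct_dataset <- function(x, r, center = TRUE, ...) {
  fit_basis(pool_embeddings(x), r = r, center = center)
}

#' @rdname fit_basis
#' @export
fit_basis.matrix <- function(x, r, center = TRUE, ...) {
  m <- nrow(x); n <- ncol(x)
  if (n < 2L) abort("need at least 2 embedding columns")
  if (r < 1L || r > min(m, n)) {
    abort(sprintf("`r` must lie in [1, %d]", min(m, n)))
  }
  mu <- rowMeans(x)
  xc <- x - mu
  sv <- svd(xc, nu = min(m, n), nv = 0)
  variances <- sv$d^2
  tol <- max(variances) * 1e-12
  num_rank <- sum(variances > tol)
  if (num_rank == 0L) {
    warn("all embeddings identical: zero scatter, basis completed arbitrarily")
    rotation <- diag(m)[, seq_len(r), drop = FALSE]
    return(new_basis(rotation, mu, rep(0, r), center))
  }
  if (r > num_rank) {
    warn(sprintf(
      "r = %d exceeds numerical rank %d; trailing variances are ~0",
      r, num_rank))
  }
  rotation <- sv$u[, seq_len(r), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(r)) {
    k <- which.max(abs(rotation[, j]))
    if (rotation[k, j] < 0) rotation[, j] <- -rotation[, j]
  }
  new_basis(rotation, mu, variances[seq_len(r)], center)
}

#' Project embeddings onto the truncated basis
#'
#' Computes `h_hat = Q^T (h - c)` where `c` is the mean embedding when
#' centering is enabled on the basis (the default) and zero otherwise.
#' Atoms whose (centered) embeddings lie in the orthogonal complement of
#' the basis project to zero and therefore receive zero parameter
#' perturbation downstream.
#'
#' @param basis A `ct_basis`.
#' @param h A length-`m` vector, or an `n_atoms x m` matrix with one
#'   embedding per row.
#' @param center Override the basis centering flag.
#' @return A length-`r` vector, or an `n_atoms x r` matrix.
#' @export
project <- function(basis, h, center = NULL) {
  stopifnot(inherits(basis, "ct_basis"))
  center <- center %||% basis$center
  m <- nrow(basis$rotation)
  if (is.matrix(h)) {
    if (ncol(h) != m) abort(sprintf("expected %d embedding columns", m))
    hc <- if (center) sweep(h, 2L, basis$mu) else h
    hc %*% basis$rotation
  } else {
    if (length(h) != m) abort(sprintf("expected an embedding of length %d", m))
    hc <- if (center) h - basis$mu else h
    drop(crossprod(basis$rotation, hc))
  }
}

#' Cumulative explained variance of a fitted basis
#' @param basis A `ct_basis`.
#' @return Tibble with `component`, `variance`, `cumulative_fraction`.
#' @export
explained_variance <- function(basis) {
  v <- basis$variances
  tibble(component = seq_along(v), variance = v,
         cumulative_fraction = if (sum(v) > 0) cumsum(v) / sum(v)
                               else rep(NA_real_, length(v)))
}
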