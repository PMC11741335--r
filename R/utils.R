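# Physical constants and numerical helpers shared across modules.
# Units are fixed package-wide: kcal/mol for energies, elementary charge e
# for charges, Angstrom for distances. No unit conversion happens inside
# the math modules.

#' Physical constants used by chargetune
#'
#' * `kB`: Boltzmann constant in kcal mol^-1 K^-1.
#' * `coulomb`: Coulomb constant in kcal A mol^-1 e^-2, the prefactor of
#'   `q_i q_j / r` when charges are in elementary charge units and
#'   distances in Angstrom.
#' * `T_default`: default temperature (K) for hydration free energies.
#'
#' @format A named list.
#' @export
ct_constants <- list(
  kB = 0.001987204259,
  coulomb = 332.0637,
  T_default = 298.15
)

#' Inverse thermal energy
#'
#' Returns beta = 1 / (kB T) in mol kcal^-1, the inverse thermal energy
#' used in all reweighting expressions. At the default 298.15 K,
#' kB T = 0.5925 kcal/mol and beta = 1.688 mol/kcal.
#'
#' @param temperature Temperature in Kelvin.
#' @return Positive scalar, mol kcal^-1.
#' @export
default_beta <- function(temperature = ct_constants$T_default) {
  stopifnot(is.numeric(temperature), temperature > 0)
  1 / (ct_constants$kB * temperature)
}

# Numerically stable log(sum(exp(x))).
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) {
    return(m)
  }
  m + log(sum(exp(x - m)))
}

# Assert a numeric vector/matrix is finite, with a readable field name.
check_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(sprintf("non-finite values in `%s`", what))
  }
  invisible(x)
}

# purrr-free compact map helpers used on hot paths.
vapply_dbl <- function(x, f, ...) vapply(x, f, numeric(1), ...)
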