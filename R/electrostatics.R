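# Low-rank perturbation of electronegativity/hardness, charge
# regeneration by charge equilibration (QEq), and a reference fully
# coupled per-atom potential calculator for toy fixtures.

#' Fine-tuning parameters
#'
#' The 2 x r perturbation matrix Theta, stored as its two rows:
#' `theta_e` perturbs electronegativities, `theta_s` perturbs hardnesses,
#' both through inner products with the projected embeddings.
#'
#' @param theta_e,theta_s Numeric vectors of equal length `r`.
#' @return An object of class `ct_params`.
#' @export
ft_params <- function(theta_e, theta_s) {
  if (length(theta_e) != length(theta_s)) {
    abort("`theta_e` and `theta_s` must have equal length")
  }
  check_finite(theta_e, "theta_e")
  check_finite(theta_s, "theta_s")
  structure(list(theta_e = as.numeric(theta_e),
                 theta_s = as.numeric(theta_s)),
            class = "ct_params")
}

#' @rdname ft_params
#' @param r Rank of the zero parameter matrix.
#' @export
zero_params <- function(r) ft_params(numeric(r), numeric(r))

#' @export
print.ct_params <- function(x, ...) {
  cat(sprintf("<ct_params> rank %d, |theta| = %.4g\n",
              length(x$theta_e), sqrt(sum(unlist(x)^2))))
  invisible(x)
}

#' @export
as.matrix.ct_params <- function(x, ...) {
  rbind(e = x$theta_e, s = x$theta_s)
}

params_norm <- function(theta) sqrt(sum(theta$theta_e^2) + sum(theta$theta_s^2))

#' Perturb electrostatic parameters
#'
#' Applies the low-rank linear perturbation
#' `e*_i = e_i + theta_e . h_hat_i`, `s*_i = s_i + theta_s . h_hat_i`.
#' Perturbations driving any hardness at or below `s_floor` are flagged
#' infeasible (QEq divides by `s*`); the objective treats such points as
#' a large sentinel loss so the line search backtracks.
#'
#' @param e,s Foundation electronegativities and hardnesses (length n).
#' @param h_hat `n x r` matrix of projected embeddings.
#' @param theta A `ct_params`.
#' @param s_floor Feasibility floor for perturbed hardness (default 1e-6).
#' @return List with `e_star`, `s_star`, and logical `feasible`.
#' @export
perturb_parameters <- function(e, s, h_hat, theta, s_floor = 1e-6) {
  stopifnot(inherits(theta, "ct_params"))
  if (!is.matrix(h_hat)) h_hat <- matrix(h_hat, nrow = length(e))
  if (nrow(h_hat) != length(e) || length(e) != length(s)) {
    abort("shapes of `e`, `s`, `h_hat` are inconsistent")
  }
  if (ncol(h_hat) != length(theta$theta_e)) {
    abort("rank of `theta` does not match `h_hat`")
  }
  e_star <- e + drop(h_hat %*% theta$theta_e)
  s_star <- s + drop(h_hat %*% theta$theta_s)
  list(e_star = e_star, s_star = s_star,
       feasible = all(s_star > s_floor))
}

#' Charge equilibration (QEq)
#'
#' Solves the charge equilibration model - a second-order expansion of a
#' fictitious electrostatic energy in the atomic charges with a Lagrange
#' multiplier enforcing the total molecular charge Q:
#' `q_i = -e_i/s_i + (1/s_i) * (Q + sum_j e_j/s_j) / (sum_j 1/s_j)`.
#' The result conserves `sum(q) = Q` to machine precision, is smooth in
#' `(e, s)`, and is invariant to adding a common constant to all
#' electronegativities.
#'
#' @param e_star,s_star Perturbed electronegativities and hardnesses;
#'   every `s_star` must be strictly positive.
#' @param Q Total molecular charge (e).
#' @return Numeric vector of partial charges.
#' @export
qeq_charges <- function(e_star, s_star, Q) {
  if (length(e_star) != length(s_star)) {
    abort("`e_star` and `s_star` must have equal length")
  }
  if (any(s_star <= 0)) abort("all hardness values must be strictly positive")
  inv_s <- 1 / s_star
  lambda <- (Q + sum(e_star * inv_s)) / sum(inv_s)
  (lambda - e_star) * inv_s
}

# Transposed-Jacobian products of QEq, used by the analytic loss
# gradient: given v (length n), returns t(dq/de*) %*% v and
# t(dq/ds*) %*% v without forming the n x n Jacobians.
qeq_jacobian_tv <- function(e_star, s_star, Q, v) {
  inv_s <- 1 / s_star
  T_sum <- sum(inv_s)
  lambda <- (Q + sum(e_star * inv_s)) / T_sum
  vs <- sum(v * inv_s)
  je_tv <- -v * inv_s + inv_s * vs / T_sum
  js_tv <- v * (e_star - lambda) * inv_s^2 +
    (lambda - e_star) * inv_s^2 * vs / T_sum
  list(e = je_tv, s = js_tv)
}

#' Perturbed charges for one molecule
#'
#' Composes projection, parameter perturbation and QEq:
#' `q*(Theta) = QEq(e + Theta_e h_hat, s + Theta_s h_hat, Q)`. At
#' `Theta = 0` this reproduces the stored foundation charges exactly
#' whenever those charges are themselves QEq-consistent with `(e, s, Q)`
#' (the synthetic generator guarantees this; [validate_dataset()] with
#' `check_qeq = TRUE` diagnoses real inputs).
#'
#' @param record A molecule record (a row of `dataset$molecules`, as a
#'   list with `embeddings`, `e`, `s`, `Q`).
#' @param basis A `ct_basis`.
#' @param theta A `ct_params`.
#' @param s_floor Feasibility floor passed to [perturb_parameters()].
#' @return Numeric vector of perturbed charges; errors if the
#'   perturbation is infeasible.
#' @export
perturbed_charges <- function(record, basis, theta, s_floor = 1e-6) {
  res <- perturbed_charges_safe(record, basis, theta, s_floor)
  if (!res$feasible) {
    abort(sprintf(
      "perturbation drives hardness below %g for molecule \"%s\"",
      s_floor, record$molecule_id %||% "?"))
  }
  res$q_star
}

# Non-throwing variant used by reweighting and the objective.
perturbed_charges_safe <- function(record, basis, theta, s_floor = 1e-6,
                                   h_hat = NULL) {
  h_hat <- h_hat %||% project(basis, record$embeddings)
  ps <- perturb_parameters(record$e, record$s, h_hat, theta, s_floor)
  if (!ps$feasible) {
    return(list(q_star = NULL, feasible = FALSE,
                e_star = ps$e_star, s_star = ps$s_star, h_hat = h_hat))
  }
  list(q_star = qeq_charges(ps$e_star, ps$s_star, record$Q),
       feasible = TRUE, e_star = ps$e_star, s_star = ps$s_star,
       h_hat = h_hat)
}

#' Toy molecule-environment configuration
#'
#' A minimal explicit-coordinate system used to produce reference
#' per-atom potentials for fixtures: molecule atom positions, environment
#' (solvent) positions and charges, and a radial cutoff beyond which
#' interactions are omitted.
#'
#' @param mol_coords `n_atoms x 3` matrix, Angstrom.
#' @param env_coords `n_env x 3` matrix, Angstrom.
#' @param env_charges Length `n_env` vector, elementary charge.
#' @param r_cut Cutoff radius, Angstrom (default 12).
#' @return An object of class `ct_toyconfig`.
#' @export
toy_configuration <- function(mol_coords, env_coords, env_charges,
                              r_cut = 12) {
  mol_coords <- as.matrix(mol_coords); env_coords <- as.matrix(env_coords)
  stopifnot(ncol(mol_coords) == 3L, ncol(env_coords) == 3L,
            nrow(env_coords) == length(env_charges), r_cut > 0)
  d <- pair_distances(mol_coords, env_coords)
  if (any(d == 0)) abort("molecule and environment atoms overlap")
  structure(list(mol_coords = mol_coords, env_coords = env_coords,
                 env_charges = as.numeric(env_charges), r_cut = r_cut),
            class = "ct_toyconfig")
}

pair_distances <- function(a, b) {
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) out <- out + outer(a[, k], b[, k], "-")^2
  sqrt(out)
}

#' Parse whitespace-delimited coordinates
#'
#' Reads XYZ-style plain text (columns `x y z` or `x y z q`, one atom per
#' line, comments with `#`) into a coordinate matrix, with charges as an
#' attribute when present.
#'
#' @param text A character scalar of lines, or a file path.
#' @return Numeric matrix `n x 3`; attribute `"charges"` if a fourth
#'   column is present.
#' @export
read_coords <- function(text) {
  lines <- if (length(text) == 1L && file.exists(text)) readLines(text)
           else unlist(strsplit(text, "\n"))
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  vals <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  ncols <- unique(lengths(vals))
  if (length(ncols) != 1L || !(ncols %in% c(3L, 4L))) {
    abort("expected 3 or 4 whitespace-delimited numeric columns")
  }
  mat <- do.call(rbind, vals)
  coords <- mat[, 1:3, drop = FALSE]
  if (ncols == 4L) attr(coords, "charges") <- mat[, 4L]
  coords
}

#' Reference per-atom environment electrostatic potential
#'
#' Computes, for each molecule atom, the charge-normalized electrostatic
#' potential generated by all environment charges within the cutoff:
#' `phi_i = sum_j C q_j f(r_ij) / r_ij` with `C = 332.0637`
#' kcal A mol^-1 e^-2, evaluated at the fully coupled state. The
#' default switching function `f(r) = cos^8((pi/2) (r/r_cut)^3)` is 1 at
#' contact and decays smoothly to 0 at the cutoff; `switch = "none"`
#' uses bare Coulomb truncated at the cutoff. The result is independent
#' of the molecule's own charges.
#'
#' @param config A [toy_configuration()].
#' @param switch `"cos8"` (default) or `"none"`.
#' @return Numeric vector of potentials, kcal mol^-1 e^-1.
#' @export
reference_phi <- function(config, switch = c("cos8", "none")) {
  stopifnot(inherits(config, "ct_toyconfig"))
  switch <- match.arg(switch)
  d <- pair_distances(config$mol_coords, config$env_coords)
  f <- switch(switch,
    cos8 = cos((pi / 2) * (d / config$r_cut)^3)^8,
    none = matrix(1, nrow(d), ncol(d)))
  contrib <- ct_constants$coulomb * f / d
  contrib[d >= config$r_cut] <- 0
  drop(contrib %*% config$env_charges)
}

#' Molecule-environment electrostatic energy of one frame
#'
#' The total electrostatic interaction energy factorizes as the inner
#' product of the molecular charges with the per-atom environment
#' potentials: `U = sum_i q*_i phi_i`, linear in the charges. This is
#' what makes one-shot reweighting possible from stored potentials.
#'
#' @param q_star Molecular partial charges (e).
#' @param phi_frame Per-atom environment potentials for one frame
#'   (kcal mol^-1 e^-1).
#' @return Scalar energy, kcal/mol.
#' @export
electrostatic_energy <- function(q_star, phi_frame) {
  if (length(q_star) != length(phi_frame)) {
    abort("`q_star` and `phi_frame` must have equal length")
  }
  sum(q_star * phi_frame)
}
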