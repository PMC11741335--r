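# Synthetic fine-tuning datasets with the statistical structure the
# method assumes: clustered atom embeddings, per-cluster electrostatic
# parameters, and Gaussian linear-response potential ensembles. The
# Gaussian ensemble makes the Zwanzig exponential average exactly
# integrable, so every reweighted quantity has a closed-form oracle.

#' Gaussian ensemble specification
#'
#' Describes the distribution the per-atom potentials of one molecule are
#' drawn from: `phi ~ Normal(mu0 - A q, Sigma_phi)` where `mu0` is the
#' baseline potential mean (kcal mol^-1 e^-1), `A` is a symmetric
#' positive-semidefinite linear solvent-response matrix
#' (kcal mol^-1 e^-2), and `Sigma_phi` is the positive-definite frame
#' covariance. Under this ensemble the perturbed free energy has the
#' closed form implemented in [exact_dg_pert()].
#'
#' @param mu0 Baseline mean potential per atom.
#' @param A Symmetric PSD response matrix.
#' @param Sigma_phi Symmetric PD covariance of the potentials.
#' @param n_frames Number of frames drawn from the ensemble.
#' @param seed Integer seed used for the draw.
#' @return A list of class `ct_ensemble_spec`.
#' @export
ensemble_spec <- function(mu0, A, Sigma_phi, n_frames = 5000, seed = 0L) {
  n <- length(mu0)
  stopifnot(is.matrix(A), is.matrix(Sigma_phi),
            all(dim(A) == n), all(dim(Sigma_phi) == n))
  if (max(abs(A - t(A))) > 1e-8) abort("`A` must be symmetric")
  if (max(abs(Sigma_phi - t(Sigma_phi))) > 1e-8) {
    abort("`Sigma_phi` must be symmetric")
  }
  ev <- eigen(Sigma_phi, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) abort("`Sigma_phi` must be positive definite")
  structure(list(mu0 = as.numeric(mu0), A = A, Sigma_phi = Sigma_phi,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "ct_ensemble_spec")
}

#' Generator configuration
#'
#' Defaults describe a desk-scale study: 200 molecules of 5-30 atoms,
#' 64-dimensional embeddings drawn around 8 chemical-environment
#' archetypes, 2000 potential frames per molecule, neutral molecules,
#' experimental noise of 0.2 kcal/mol, and a hidden perturbation of rank
#' 5 expressed in the generator's own PCA basis.
#'
#' @param n_molecules Number of molecules.
#' @param atoms_min,atoms_max Atom-count range (uniform).
#' @param m Embedding dimension.
#' @param n_clusters Number of embedding archetypes.
#' @param n_frames Potential frames per molecule.
#' @param rank Rank of the PCA basis in which `theta_true` lives.
#' @param theta_true Hidden perturbation: a `ct_params` of rank `rank`,
#'   `"random"` (drawn from `Normal(0, theta_sd^2)` entries), or `NULL`
#'   for the zero perturbation.
#' @param theta_sd Entry scale used when `theta_true = "random"`.
#' @param expt_noise_sd Gaussian noise added to synthetic experimental
#'   free energies, kcal/mol.
#' @param overlap_scale Multiplier on the potential fluctuation scale;
#'   larger values shrink phase-space overlap and make reweighting
#'   ESS-fragile.
#' @param beta Inverse thermal energy, mol kcal^-1.
#' @param seed Integer seed; the generator is fully deterministic
#'   given it.
#' @return A list of class `ct_generator_config`.
#' @export
generator_config <- function(n_molecules = 200, atoms_min = 5,
                             atoms_max = 30, m = 64, n_clusters = 8,
                             n_frames = 2000, rank = 5,
                             theta_true = "random", theta_sd = 0.5,
                             expt_noise_sd = 0.2, overlap_scale = 1,
                             beta = default_beta(), seed = 1L) {
  stopifnot(n_molecules >= 1, atoms_min >= 1, atoms_max >= atoms_min,
            m >= 2, n_clusters >= 1, n_frames >= 2, rank >= 1,
            expt_noise_sd >= 0, overlap_scale > 0, beta > 0)
  if (inherits(theta_true, "ct_params") &&
      length(theta_true$theta_e) != rank) {
    abort("`theta_true` rank must match `rank`")
  }
  structure(
    list(n_molecules = n_molecules, atoms_min = atoms_min,
         atoms_max = atoms_max, m = m, n_clusters = n_clusters,
         n_frames = n_frames, rank = rank, theta_true = theta_true,
         theta_sd = theta_sd, expt_noise_sd = expt_noise_sd,
         overlap_scale = overlap_scale, beta = beta,
         seed = as.integer(seed)),
    class = "ct_generator_config")
}

# Draw the dataset-level archetypes: embedding cluster centers and
# per-cluster electronegativity/hardness. Electronegativities spread
# ~40 kcal/mol/e across clusters (charges only feel differences),
# hardnesses sit in the 150-300 kcal/mol/e^2 range typical of QEq
# parameterizations.
draw_archetypes <- function(config) {
  list(
    centers = matrix(rnorm(config$n_clusters * config$m, sd = 2),
                     config$n_clusters, config$m),
    e_mean = rnorm(config$n_clusters, mean = 120, sd = 40),
    s_mean = runif(config$n_clusters, 150, 300))
}

#' Generate one synthetic molecule
#'
#' Draws atom cluster assignments, embeddings (archetype + Gaussian
#' jitter), per-atom electrostatic parameters, QEq-consistent charges at
#' total charge `Q = 0` (neutral organics), a Gaussian ensemble
#' specification, and the potential frames
#' `phi ~ Normal(mu0 - A q, Sigma_phi)`. The record satisfies every
#' dataset invariant by construction; stored charges are exactly
#' `qeq_charges(e, s, 0)` so the zero-perturbation identity is exact.
#'
#' @param config A [generator_config()].
#' @param archetypes Output of the internal archetype draw; drawn fresh
#'   (from the current RNG state) when `NULL`.
#' @param molecule_id Identifier for the record.
#' @return List with `record` (a one-row tibble of the dataset schema)
#'   and `spec` (the `ct_ensemble_spec`).
#' @export
generate_molecule <- function(config, archetypes = NULL,
                              molecule_id = "mol_1") {
  stopifnot(inherits(config, "ct_generator_config"))
  archetypes <- archetypes %||% draw_archetypes(config)
  n <- config$atoms_min +
    sample.int(config$atoms_max - config$atoms_min + 1L, 1L) - 1L
  k <- sample.int(config$n_clusters, n, replace = TRUE)
  emb <- archetypes$centers[k, , drop = FALSE] +
    matrix(rnorm(n * config$m, sd = 0.3), n, config$m)
  e <- archetypes$e_mean[k] + rnorm(n, sd = 8)
  s <- pmax(archetypes$s_mean[k] + rnorm(n, sd = 15), 0.1)
  q <- qeq_charges(e, s, 0)
  mu0 <- rnorm(n, sd = 15)
  A <- 30 * (0.9 * diag(n) + 0.1 * matrix(1, n, n) / n)
  sd_phi <- runif(n, 4, 8) * config$overlap_scale
  corr <- 0.3^abs(outer(seq_len(n), seq_len(n), "-"))
  Sigma <- diag(sd_phi) %*% corr %*% diag(sd_phi)
  Sigma <- (Sigma + t(Sigma)) / 2
  spec <- ensemble_spec(mu0, A, Sigma, n_frames = config$n_frames,
                        seed = config$seed)
  mu <- mu0 - drop(A %*% q)
  phi <- MASS::mvrnorm(config$n_frames, mu = mu, Sigma = Sigma)
  dimnames(phi) <- NULL
  record <- tibble(
    molecule_id = molecule_id, n_atoms = as.integer(n), Q = 0,
    dG_calc = runif(1, -15, 2), dG_calc_unc = 0.02,
    dG_expt = NA_real_, dG_expt_unc = config$expt_noise_sd,
    split = "train",
    embeddings = list(emb), e = list(e), s = list(s), q = list(q),
    phi = list(phi), spec = list(spec))
  list(record = record, spec = spec)
}

#' Exact perturbed free energy under the Gaussian ensemble
#'
#' Closed form of the Zwanzig exponential average when the potentials
#' are Gaussian: with `dq = q_star - q` and `mu = mu0 - A q`,
#' `dG = dq' mu - (beta/2) dq' Sigma_phi dq`. Serves as ground truth for
#' reweighting and as the "re-simulated" reference in consistency
#' checks.
#'
#' @param spec A `ct_ensemble_spec`.
#' @param q,q_star Foundation and perturbed charges.
#' @param beta Inverse thermal energy.
#' @return Scalar free-energy perturbation, kcal/mol.
#' @export
exact_dg_pert <- function(spec, q, q_star, beta) {
  stopifnot(inherits(spec, "ct_ensemble_spec"))
  dq <- q_star - q
  mu <- spec$mu0 - drop(spec$A %*% q)
  sum(dq * mu) - (beta / 2) * drop(crossprod(dq, spec$Sigma_phi %*% dq))
}

#' Exact Zwanzig sampling error under the Gaussian ensemble
#'
#' Delta-method standard error of the `N`-frame Zwanzig estimate when
#' `dU` is Gaussian with variance `dq' Sigma_phi dq`:
#' `se = sqrt((exp(beta^2 sigma^2) - 1) / N) / beta`.
#'
#' @inheritParams exact_dg_pert
#' @param n Number of frames.
#' @return Scalar standard error, kcal/mol.
#' @export
exact_zwanzig_stderr <- function(spec, q, q_star, beta, n) {
  dq <- q_star - q
  sigma2 <- drop(crossprod(dq, spec$Sigma_phi %*% dq))
  sqrt(expm1(beta^2 * sigma2) / n) / beta
}

#' Sample the exponentially tilted (perturbed) ensemble
#'
#' Draws fresh potential frames from the ensemble a re-simulation at the
#' perturbed charges would sample. For a Gaussian base ensemble the
#' tilt is exact and Gaussian:
#' `Normal(mu0 - A q - beta Sigma_phi dq, Sigma_phi)`.
#'
#' @inheritParams exact_dg_pert
#' @param n Number of frames to draw.
#' @return `n x n_atoms` matrix of potentials.
#' @export
sample_perturbed_ensemble <- function(spec, q, q_star, beta, n) {
  dq <- q_star - q
  mu <- spec$mu0 - drop(spec$A %*% q) - beta * drop(spec$Sigma_phi %*% dq)
  MASS::mvrnorm(n, mu = mu, Sigma = spec$Sigma_phi)
}

#' Generate a complete synthetic fine-tuning dataset
#'
#' End-to-end fixture factory: draws molecules, fits the generator's own
#' PCA basis on the pooled embeddings, resolves the hidden perturbation
#' `theta_true` in that basis, computes each molecule's ground-truth
#' perturbed charges and exact perturbed free energy, and sets
#' `dG_expt = dG_calc + dG_exact(theta_true) + Normal(0, expt_noise_sd)`.
#' Baseline calculated free energies are drawn from a broad uniform
#' range emulating hydration free-energy benchmarks. Ground-truth
#' charges are stored per molecule in column `q_true` and `theta_true`
#' in the metadata; the whole construction is deterministic given the
#' config seed.
#'
#' @param config A [generator_config()].
#' @return A `ct_dataset` (all molecules initially in the train split;
#'   use [assign_splits()]).
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "ct_generator_config"))
  withr::with_seed(config$seed, {
    archetypes <- draw_archetypes(config)
    gen <- lapply(seq_len(config$n_molecules), function(i) {
      generate_molecule(config, archetypes,
                        molecule_id = sprintf("mol_%04d", i))
    })
    molecules <- dplyr::bind_rows(lapply(gen, `[[`, "record"))
    ds <- ct_dataset(molecules, beta = config$beta, m = config$m,
                     validate = FALSE)
    basis <- fit_basis(ds, r = config$rank)
    theta_true <- resolve_theta_true(config)
    mol <- ds$molecules
    q_true <- vector("list", nrow(mol))
    for (i in seq_len(nrow(mol))) {
      rec <- get_record(ds, i)
      pc <- perturbed_charges_safe(rec, basis, theta_true)
      if (!pc$feasible) {
        abort(sprintf(
          "theta_true is infeasible (hardness <= 0) for molecule \"%s\"",
          rec$molecule_id))
      }
      q_true[[i]] <- pc$q_star
      dg_exact <- exact_dg_pert(rec$spec, rec$q, pc$q_star, config$beta)
      mol$dG_expt[[i]] <- mol$dG_calc[[i]] + dg_exact +
        rnorm(1, sd = config$expt_noise_sd)
    }
    mol$q_true <- q_true
    meta <- list(
      generator = config[setdiff(names(config), "theta_true")],
      theta_true = list(theta_e = theta_true$theta_e,
                        theta_s = theta_true$theta_s),
      temperature = 1 / (ct_constants$kB * config$beta),
      pca = list(rank = config$rank, center = TRUE,
                 pooled = "all molecules"),
      seed = config$seed)
    ct_dataset(mol, beta = config$beta, m = config$m, metadata = meta)
  })
}

resolve_theta_true <- function(config) {
  tt <- config$theta_true
  if (is.null(tt)) return(zero_params(config$rank))
  if (inherits(tt, "ct_params")) return(tt)
  if (identical(tt, "random")) {
    return(ft_params(rnorm(config$rank, sd = config$theta_sd),
                     rnorm(config$rank, sd = config$theta_sd)))
  }
  abort("`theta_true` must be a ct_params, \"random\", or NULL")
}

#' Hidden perturbation stored by the generator
#'
#' Reconstructs the `ct_params` the generator used from dataset
#' metadata.
#'
#' @param dataset A synthetic `ct_dataset`.
#' @return A `ct_params`.
#' @export
true_params <- function(dataset) {
  tt <- dataset$metadata$theta_true
  if (is.null(tt)) abort("dataset carries no generator ground truth")
  ft_params(unlist(tt$theta_e), unlist(tt$theta_s))
}
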