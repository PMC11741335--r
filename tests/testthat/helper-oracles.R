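# Independent oracles and shared fixtures. Oracles are deliberately
# naive (explicit loops, no shared code with the implementation).

# Small synthetic dataset used across suites.
tiny_dataset <- function(n_molecules = 6, n_frames = 120, m = 12,
                         rank = 2, seed = 7, theta_true = "random",
                         theta_sd = 0.5, overlap_scale = 1,
                         expt_noise_sd = 0.2, atoms_min = 4,
                         atoms_max = 8) {
  generate_dataset(generator_config(
    n_molecules = n_molecules, atoms_min = atoms_min,
    atoms_max = atoms_max, m = m, n_clusters = 3, n_frames = n_frames,
    rank = rank, theta_true = theta_true, theta_sd = theta_sd,
    expt_noise_sd = expt_noise_sd, overlap_scale = overlap_scale,
    seed = seed))
}

# Loss config compatible with short frame counts in unit tests.
tiny_loss_config <- function(n_frames = 120,
                             a_onset = round(0.6 * n_frames),
                             ess_stop = round(0.4 * n_frames), ...) {
  loss_config(a_onset = a_onset, ess_stop = ess_stop, ...)
}

# Central finite differences of the total loss w.r.t. theta.
fd_loss_gradient <- function(dataset, basis, theta, config,
                             eps = 1e-6) {
  r <- length(theta$theta_e)
  out <- matrix(0, 2, r, dimnames = list(c("e", "s"), NULL))
  for (row in 1:2) {
    for (j in seq_len(r)) {
      tp <- theta; tm <- theta
      field <- if (row == 1) "theta_e" else "theta_s"
      tp[[field]][j] <- tp[[field]][j] + eps
      tm[[field]][j] <- tm[[field]][j] - eps
      out[row, j] <-
        (total_loss(dataset, basis, tp, config)$loss -
           total_loss(dataset, basis, tm, config)$loss) / (2 * eps)
    }
  }
  out
}

# Direct unvectorized Zwanzig average (safe only for tame inputs).
brute_zwanzig <- function(delta_u, beta) {
  acc <- 0
  for (u in delta_u) acc <- acc + exp(-beta * u)
  -log(acc / length(delta_u)) / beta
}

# Riemann-Stieltjes integral of (F_a - F_b)^2 dF_b over the empirical
# CDFs, evaluated point by point.
brute_cvm_integral <- function(a, b) {
  total <- 0
  for (x in b) {
    fa <- sum(a <= x) / length(a)
    fb <- sum(b <= x) / length(b)
    total <- total + (fa - fb)^2 / length(b)
  }
  total
}

# Double loop over molecule-environment pairs for the toy potential.
brute_pair_energy <- function(q_mol, config, switch = "cos8") {
  total <- 0
  for (i in seq_len(nrow(config$mol_coords))) {
    for (j in seq_len(nrow(config$env_coords))) {
      r <- sqrt(sum((config$mol_coords[i, ] - config$env_coords[j, ])^2))
      if (r >= config$r_cut) next
      f <- if (switch == "cos8") cos((pi / 2) * (r / config$r_cut)^3)^8
           else 1
      total <- total + 332.0637 * q_mol[i] * config$env_charges[j] * f / r
    }
  }
  total
}

# Gauss-type numerical quadrature of the 1-D Gaussian exponential
# average, used to corroborate the closed-form oracle.
quadrature_gaussian_dg <- function(mu, sigma2, beta, dq = 1) {
  # dU = dq * phi with phi ~ N(mu, sigma2)
  integrand <- function(phi) {
    exp(-beta * dq * phi) * stats::dnorm(phi, mu, sqrt(sigma2))
  }
  val <- stats::integrate(integrand, mu - 12 * sqrt(sigma2),
                          mu + 12 * sqrt(sigma2),
                          rel.tol = 1e-12)$value
  -log(val) / beta
}
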