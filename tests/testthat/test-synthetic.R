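test_that("generated records satisfy every dataset invariant", {
  for (seed in 1:100) {
    cfg <- generator_config(n_molecules = 1, atoms_min = 3,
                            atoms_max = 12, m = 8, n_clusters = 2,
                            n_frames = 5, rank = 2, seed = seed)
    out <- withr::with_seed(seed, generate_molecule(cfg))
    rec <- out$record
    expect_true(all(rec$s[[1]] > 0))
    expect_lt(abs(sum(rec$q[[1]]) - rec$Q), 1e-8)
    expect_equal(dim(rec$phi[[1]]), c(5L, rec$n_atoms))
    expect_equal(ncol(rec$embeddings[[1]]), 8)
  }
})

test_that("frame means obey the linear-response law of large numbers", {
  cfg <- generator_config(n_molecules = 1, atoms_min = 6, atoms_max = 6,
                          m = 8, n_frames = 5000, rank = 2, seed = 17)
  out <- withr::with_seed(17, generate_molecule(cfg))
  spec <- out$spec
  q <- out$record$q[[1]]
  mu <- spec$mu0 - drop(spec$A %*% q)
  centered <- colMeans(out$record$phi[[1]]) - mu
  stderr <- sqrt(diag(spec$Sigma_phi) / 5000)
  expect_true(all(abs(centered) < 4 * stderr))
})

test_that("same-cluster embeddings are closer than cross-cluster", {
  cfg <- generator_config(n_molecules = 2, m = 16, n_clusters = 4,
                          n_frames = 5, rank = 2, seed = 19)
  gaps <- withr::with_seed(19, {
    arch <- chargetune:::draw_archetypes(cfg)
    # two atoms from cluster 1, one from cluster 2
    h <- rbind(
      arch$centers[1, ] + rnorm(16, sd = 0.3),
      arch$centers[1, ] + rnorm(16, sd = 0.3),
      arch$centers[2, ] + rnorm(16, sd = 0.3))
    c(within = sqrt(sum((h[1, ] - h[2, ])^2)),
      across = sqrt(sum((h[1, ] - h[3, ])^2)))
  })
  expect_lt(gaps["within"], gaps["across"])
})

test_that("the closed-form oracle integrates the Gaussian average", {
  n <- 3
  spec <- ensemble_spec(mu0 = c(1, -2, 0.5),
                        A = diag(n) * 2,
                        Sigma_phi = diag(c(0.3, 0.5, 0.2)),
                        n_frames = 10, seed = 1)
  q <- c(0.1, -0.1, 0)
  expect_equal(exact_dg_pert(spec, q, q, 1.5), 0)
  # one-atom case evaluates the textbook expression and the quadrature
  spec1 <- ensemble_spec(2, matrix(0, 1, 1), matrix(0.25, 1, 1),
                         10, 1)
  dg <- exact_dg_pert(spec1, 0, 1, 1)
  expect_equal(dg, 2 - 0.125)
  expect_equal(dg, quadrature_gaussian_dg(2, 0.25, 1), tolerance = 1e-9)
  # deterministic (zero-covariance) limit is pure mean-field
  spec_det <- ensemble_spec(c(1, -1), diag(2), diag(2) * 1e-12, 10, 1)
  dq <- c(0.2, 0.3)
  mu <- spec_det$mu0 - drop(spec_det$A %*% q[1:2])
  expect_equal(exact_dg_pert(spec_det, q[1:2], q[1:2] + dq, 1),
               sum(dq * mu), tolerance = 1e-9)
  expect_error(ensemble_spec(c(1, 2), diag(2), -diag(2), 10, 1),
               "positive definite")
})

test_that("tilted-ensemble sampling matches the reweighting identities", {
  spec <- ensemble_spec(mu0 = c(2, -1),
                        A = matrix(c(3, 0.5, 0.5, 3), 2),
                        Sigma_phi = matrix(c(1, 0.3, 0.3, 0.8), 2),
                        n_frames = 10, seed = 1)
  q <- c(0.2, -0.2)
  beta <- 1.2
  dq <- c(0.15, -0.05)
  q_star <- q + dq
  tilt_mu <- spec$mu0 - drop(spec$A %*% q) -
    beta * drop(spec$Sigma_phi %*% dq)
  # sample mean converges to the tilted mean
  draws <- withr::with_seed(3, {
    sample_perturbed_ensemble(spec, q, q_star, beta, 1e5)
  })
  stderr <- sqrt(diag(spec$Sigma_phi) / 1e5)
  expect_true(all(abs(colMeans(draws) - tilt_mu) < 4 * stderr))

  # zero perturbation leaves the distribution untouched (CvM on large
  # draws not significant in most seeds)
  hits <- 0
  for (s in 1:10) {
    base <- withr::with_seed(s, {
      sample_perturbed_ensemble(spec, q, q, beta, 400)
    })
    fresh <- withr::with_seed(100 + s, {
      MASS::mvrnorm(400, spec$mu0 - drop(spec$A %*% q), spec$Sigma_phi)
    })
    if (cramer_von_mises(base[, 1], fresh[, 1])$pvalue > 0.05) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 9)

  # importance-sampling identity: reweighted base-ensemble averages of
  # the potentials reproduce the tilted mean
  base <- withr::with_seed(11, {
    MASS::mvrnorm(2e5, spec$mu0 - drop(spec$A %*% q), spec$Sigma_phi)
  })
  lw <- -beta * drop(base %*% dq)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  reweighted_mean <- drop(crossprod(base, w))
  expect_equal(reweighted_mean, tilt_mu, tolerance = 0.02)
})

test_that("dataset generation wires the oracle into the labels", {
  # zero hidden perturbation and zero noise: exact zero residuals
  ds0 <- tiny_dataset(n_molecules = 4, n_frames = 20, seed = 131,
                      theta_true = NULL, expt_noise_sd = 0)
  expect_equal(ds0$molecules$dG_expt, ds0$molecules$dG_calc)
  # nonzero hidden perturbation: residuals follow the oracle sign
  ds1 <- tiny_dataset(n_molecules = 6, n_frames = 20, seed = 131,
                      expt_noise_sd = 0)
  basis <- fit_basis(ds1, 2)
  tt <- true_params(ds1)
  for (i in 1:6) {
    rec <- chargetune:::get_record(ds1, i)
    dg <- exact_dg_pert(rec$spec, rec$q, rec$q_true, ds1$beta)
    expect_equal(rec$dG_expt - rec$dG_calc, dg, tolerance = 1e-10)
  }
  # bit-identical regeneration under the same seed
  cfg <- generator_config(n_molecules = 3, n_frames = 15, m = 8,
                          rank = 2, seed = 7)
  a <- generate_dataset(cfg); b <- generate_dataset(cfg)
  expect_identical(a$molecules$phi, b$molecules$phi)
  expect_identical(a$molecules$dG_expt, b$molecules$dG_expt)
  expect_identical(a$metadata$theta_true, b$metadata$theta_true)
})

test_that("infeasible hidden perturbations fail loudly", {
  cfg <- generator_config(n_molecules = 2, n_frames = 10, m = 8,
                          rank = 2, seed = 7,
                          theta_true = ft_params(c(0, 0), c(-500, 0)))
  expect_error(generate_dataset(cfg), "infeasible")
})
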