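test_that("parameter perturbation is the stated linear map", {
  e <- c(1); s <- c(2)
  h_hat <- matrix(c(1, 0), 1, 2)
  th <- ft_params(c(0.5, 9), c(-0.5, 9))
  out <- perturb_parameters(e, s, h_hat, th)
  expect_equal(out$e_star, 1.5)
  expect_equal(out$s_star, 1.5)
  expect_true(out$feasible)

  # zero perturbation is the identity
  z <- perturb_parameters(c(1, 2), c(3, 4), matrix(rnorm(4), 2, 2),
                          zero_params(2))
  expect_identical(z$e_star, c(1, 2))
  expect_identical(z$s_star, c(3, 4))

  # embeddings orthogonal to both rows perturb nothing
  th2 <- ft_params(c(1, 0), c(2, 0))
  hh <- matrix(c(0, 0, 5, -3), 2, 2)  # lives in the second coordinate
  out2 <- perturb_parameters(c(1, 2), c(3, 4), hh, th2)
  expect_equal(out2$e_star, c(1, 2))

  # hardness crossing the floor is flagged
  out3 <- perturb_parameters(1, 0.5, matrix(1), ft_params(0, -1))
  expect_false(out3$feasible)
})

test_that("QEq charges solve the constrained equilibration", {
  expect_equal(qeq_charges(c(1, 2), c(1, 1), 0), c(0.5, -0.5))
  # uniform parameters share charge equally
  expect_equal(qeq_charges(rep(2.3, 5), rep(7.7, 5), 1.5),
               rep(0.3, 5))
  # a single atom carries the total charge
  expect_equal(qeq_charges(3.2, 5.1, -1), -1)
  expect_error(qeq_charges(c(1, 2), c(1, 0), 0), "positive")
})

test_that("QEq conserves total charge over random draws", {
  set.seed(101)
  worst <- 0
  for (k in 1:1000) {
    n <- sample(2:40, 1)
    e <- rnorm(n, sd = 50)
    s <- runif(n, 0.5, 300)
    Q <- runif(1, -2, 2)
    q <- qeq_charges(e, s, Q)
    worst <- max(worst, abs(sum(q) - Q))
  }
  expect_lt(worst, 1e-10)
})

test_that("QEq is invariant to a global electronegativity shift", {
  set.seed(9)
  e <- rnorm(8, sd = 30); s <- runif(8, 50, 300)
  q1 <- qeq_charges(e, s, 0.5)
  q2 <- qeq_charges(e + 17.3, s, 0.5)
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("perturbed charges reproduce foundation and oracle charges", {
  ds <- tiny_dataset(n_molecules = 4, n_frames = 20, seed = 21)
  basis <- fit_basis(ds, 2)
  rec <- chargetune:::get_record(ds, 1)
  # QEq-consistent records reproduce stored charges exactly at theta 0
  expect_identical(perturbed_charges(rec, basis, zero_params(2)), rec$q)
  # generator-stored ground-truth charges at theta_true
  tt <- true_params(ds)
  for (i in 1:4) {
    r <- chargetune:::get_record(ds, i)
    expect_equal(perturbed_charges(r, basis, tt), r$q_true,
                 tolerance = 1e-12)
  }
  # inconsistent stored charges are diagnosed at validation
  bad <- ds
  shift <- c(0.001, -0.001, rep(0, rec$n_atoms - 2))
  bad$molecules$q[[1]] <- bad$molecules$q[[1]] + shift
  expect_warning(validate_dataset(bad, check_qeq = TRUE),
                 "QEq-consistent")
})

test_that("reference potential matches Coulomb and respects the cutoff", {
  cfg <- toy_configuration(
    mol_coords = matrix(c(0, 0, 0), 1, 3),
    env_coords = matrix(c(1, 0, 0), 1, 3),
    env_charges = 1)
  expect_equal(reference_phi(cfg, "none"), 332.0637)
  # smooth switch is below bare Coulomb but close at short range
  expect_lt(reference_phi(cfg, "cos8"), 332.0637)
  expect_gt(reference_phi(cfg, "cos8"), 0.99 * 332.0637)

  # atom beyond 12 A contributes nothing
  cfg2 <- toy_configuration(
    mol_coords = matrix(0, 1, 3),
    env_coords = rbind(c(2, 0, 0), c(13, 0, 0)),
    env_charges = c(0.5, 4))
  only_near <- toy_configuration(matrix(0, 1, 3),
                                 matrix(c(2, 0, 0), 1, 3), 0.5)
  expect_equal(reference_phi(cfg2), reference_phi(only_near))

  # linearity in environment charges
  cfg3 <- toy_configuration(matrix(0, 1, 3),
                            matrix(c(2, 0, 0), 1, 3), 1.0)
  expect_equal(2 * reference_phi(cfg3),
               reference_phi(toy_configuration(matrix(0, 1, 3),
                                               matrix(c(2, 0, 0), 1, 3),
                                               2.0)))
  expect_error(toy_configuration(matrix(0, 1, 3), matrix(0, 1, 3), 1),
               "overlap")
})

test_that("factorized energy equals the brute-force pair sum", {
  set.seed(31)
  cfg <- toy_configuration(
    mol_coords = matrix(runif(5 * 3, -3, 3), 5, 3),
    env_coords = matrix(runif(40 * 3, -14, 14), 40, 3),
    env_charges = runif(40, -0.8, 0.8))
  q_mol <- runif(5, -0.5, 0.5)
  for (sw in c("cos8", "none")) {
    expect_equal(electrostatic_energy(q_mol, reference_phi(cfg, sw)),
                 brute_pair_energy(q_mol, cfg, sw), tolerance = 1e-9)
  }
})

test_that("electrostatic energy is a linear inner product", {
  expect_equal(electrostatic_energy(rep(0, 4), rnorm(4)), 0)
  expect_equal(electrostatic_energy(1, 332.0637), 332.0637)
  qa <- rnorm(6); qb <- rnorm(6); phi <- rnorm(6)
  expect_equal(electrostatic_energy(qa + qb, phi),
               electrostatic_energy(qa, phi) +
                 electrostatic_energy(qb, phi))
  expect_error(electrostatic_energy(1:3, 1:4), "length")
})

test_that("coordinate text parses into matrices", {
  txt <- "# env atoms\n0 0 0 0.4\n1.5 0 0 -0.4\n"
  xyz <- read_coords(txt)
  expect_equal(dim(xyz), c(2L, 3L))
  expect_equal(attr(xyz, "charges"), c(0.4, -0.4))
  expect_error(read_coords("1 2\n"), "columns")
})
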