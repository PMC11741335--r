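test_that("pseudo-Huber loss has the closed form and linear tails", {
  expect_equal(pseudo_huber(0, 1), 0)
  expect_equal(pseudo_huber(1, 1), sqrt(2) - 1)
  expect_equal(pseudo_huber(-1, 1), sqrt(2) - 1)
  x <- 1e6
  expect_equal(pseudo_huber(x, 0.7) / x, 0.7, tolerance = 1e-3)
  # quadratic near zero: L(x) ~ x^2/2
  expect_equal(pseudo_huber(1e-4, 1), 1e-8 / 2, tolerance = 1e-4)
})

test_that("ESS penalty is flat above onset and quadratic below", {
  cfg <- loss_config(k_reg = 100, a_onset = 750, ess_stop = 500)
  expect_equal(ess_penalty(750, cfg), 0)
  expect_equal(ess_penalty(5000, cfg), 0)
  expect_equal(ess_penalty(749, cfg), 100)
  expect_equal(ess_penalty(700, cfg), 100 * 50^2)
  # C1 at the onset: derivative approaches 0 from below
  eps <- 1e-8
  expect_lt(abs(ess_penalty(750 - eps, cfg) - ess_penalty(750, cfg)) / eps,
            1e-3)
  # smooth variant stays close to the hinge deep in the penalty region
  cfg_s <- loss_config(k_reg = 100, a_onset = 750, ess_stop = 500,
                       smooth_penalty = TRUE)
  expect_equal(ess_penalty(600, cfg_s), ess_penalty(600, cfg),
               tolerance = 1e-6)
  expect_gt(ess_penalty(750, cfg_s), 0)  # smooth tail above onset
})

test_that("loss config validates its invariants", {
  expect_error(loss_config(ess_stop = 800, a_onset = 750), "ess_stop")
  expect_error(loss_config(delta = -1), "delta")
  # a_onset must sit below the frame count of every molecule
  ds <- tiny_dataset(n_molecules = 4, n_frames = 50)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 1))
  basis <- fit_basis(ds, 2)
  expect_error(
    total_loss(ds, basis, zero_params(2),
               loss_config(a_onset = 80, ess_stop = 40)),
    "frame count")
})

test_that("total loss at zero theta is the baseline data loss", {
  ds <- tiny_dataset(n_molecules = 6, n_frames = 120, seed = 37)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 4))
  basis <- fit_basis(ds, 2)
  cfg <- tiny_loss_config(120)
  out <- total_loss(ds, basis, zero_params(2), cfg)
  expect_equal(out$reg_loss, 0)
  train <- ds$molecules$split == "train"
  resid0 <- (ds$molecules$dG_expt - ds$molecules$dG_calc)[train]
  expect_equal(out$loss,
               mean(pseudo_huber(ds$beta * resid0, cfg$delta)))
  # kcal units flag changes the scale accordingly
  cfg_kcal <- tiny_loss_config(120, loss_units = "kcal")
  out2 <- total_loss(ds, basis, zero_params(2), cfg_kcal)
  expect_equal(out2$loss, mean(pseudo_huber(resid0, cfg_kcal$delta)))
})

test_that("non-training residuals never enter the data term", {
  ds <- tiny_dataset(n_molecules = 6, n_frames = 120, seed = 41)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 4))
  basis <- fit_basis(ds, 2)
  cfg <- tiny_loss_config(120)
  th <- true_params(ds)
  base <- total_loss(ds, basis, th, cfg)
  tweaked <- ds
  i_test <- which(tweaked$molecules$split != "train")[1]
  tweaked$molecules$dG_expt[i_test] <-
    tweaked$molecules$dG_expt[i_test] + 50
  out <- total_loss(tweaked, basis, th, cfg)
  expect_identical(out$loss, base$loss)
})

test_that("zero residuals and zero theta give zero loss", {
  ds <- tiny_dataset(n_molecules = 4, n_frames = 60, seed = 43,
                     theta_true = NULL, expt_noise_sd = 0)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 1))
  basis <- fit_basis(ds, 2)
  out <- total_loss(ds, basis, zero_params(2), tiny_loss_config(60))
  expect_equal(out$loss, 0)
})

test_that("infeasible perturbations return the sentinel loss", {
  ds <- tiny_dataset(n_molecules = 4, n_frames = 60, seed = 47)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 1))
  basis <- fit_basis(ds, 2)
  bad <- ft_params(c(0, 0), c(-1e5, 0))
  out <- total_loss(ds, basis, bad, tiny_loss_config(60))
  expect_false(out$feasible)
  expect_equal(out$loss, 1e10)
  expect_error(loss_gradient(ds, basis, bad, tiny_loss_config(60)),
               "infeasible")
})

test_that("analytic gradient matches finite differences", {
  # 20 random small instances spanning flat and active penalty regions
  set.seed(53)
  worst <- 0
  for (k in 1:20) {
    ds <- tiny_dataset(n_molecules = 4, n_frames = 60, m = 8,
                       atoms_min = 3, atoms_max = 6, seed = 500 + k,
                       theta_sd = 0.4, overlap_scale = 1.3)
    ds <- suppressWarnings(assign_splits(ds, 0.5, k))
    basis <- fit_basis(ds, 2)
    cfg <- tiny_loss_config(60)
    th <- ft_params(rnorm(2, sd = 0.3), rnorm(2, sd = 0.3))
    g <- loss_gradient(ds, basis, th, cfg)
    fd <- fd_loss_gradient(ds, basis, th, cfg)
    rel <- max(abs(g - fd) / pmax(abs(fd), 1e-6))
    worst <- max(worst, rel)
  }
  expect_lt(worst, 1e-5)
})

test_that("gradient vanishes where it must", {
  ds <- tiny_dataset(n_molecules = 4, n_frames = 60, seed = 59,
                     theta_true = NULL, expt_noise_sd = 0)
  ds <- suppressWarnings(assign_splits(ds, 0.5, 1))
  basis <- fit_basis(ds, 2)
  g <- loss_gradient(ds, basis, zero_params(2), tiny_loss_config(60))
  expect_equal(max(abs(g)), 0, tolerance = 1e-10)
  # regularization contributes nothing in the flat region
  ds2 <- tiny_dataset(n_molecules = 4, n_frames = 60, seed = 61)
  ds2 <- suppressWarnings(assign_splits(ds2, 0.5, 1))
  basis2 <- fit_basis(ds2, 2)
  cfg_on <- tiny_loss_config(60, k_reg = 100)
  cfg_off <- tiny_loss_config(60, k_reg = 0)
  th <- ft_params(c(0.05, 0), c(0, 0.05))
  ess <- total_loss(ds2, basis2, th, cfg_on)$per_molecule$ess
  if (all(ess >= cfg_on$a_onset)) {
    expect_equal(loss_gradient(ds2, basis2, th, cfg_on),
                 loss_gradient(ds2, basis2, th, cfg_off))
  }
})
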