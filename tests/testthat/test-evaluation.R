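test_that("accuracy statistics have the right arithmetic", {
  st <- accuracy_stats(c(3, -4), n_boot = 200, seed = 1)
  expect_equal(st$rmse, sqrt(12.5))
  expect_equal(st$mue, 3.5)
  st0 <- accuracy_stats(rep(0, 5), n_boot = 200, seed = 1)
  expect_equal(st0$rmse, 0)
  expect_equal(st0$mue, 0)
  expect_equal(st0$rmse_lo, 0)
  expect_equal(st0$rmse_hi, 0)
  stc <- accuracy_stats(rep(-1.3, 4), n_boot = 200, seed = 1)
  expect_equal(stc$rmse, 1.3)
  expect_equal(stc$mue, 1.3)
  # rmse >= mue, and CIs contain the point estimate
  set.seed(7)
  for (k in 1:10) {
    r <- rnorm(sample(3:30, 1))
    st <- accuracy_stats(r, n_boot = 300, seed = k)
    expect_gte(st$rmse, st$mue)
    expect_gte(st$rmse, st$rmse_lo)
    expect_lte(st$rmse, st$rmse_hi)
    expect_gte(st$mue, st$mue_lo)
    expect_lte(st$mue, st$mue_hi)
  }
  expect_error(accuracy_stats(1), "at least 2")
})

test_that("Cramer-von Mises criterion: identities and oracle", {
  cv <- cramer_von_mises(c(1, 2, 3), c(1, 2, 3))
  expect_equal(cv$omega2, 0)
  # order invariance
  expect_equal(cramer_von_mises(c(2, 1), c(1, 2))$omega2, 0)
  # the spaced example evaluates exactly against the ECDF integral
  cv2 <- cramer_von_mises(c(0, 1, 2), c(10, 11, 12))
  expect_equal(cv2$omega2, 5 / 27)
  expect_equal(cv2$omega2, brute_cvm_integral(c(0, 1, 2), c(10, 11, 12)),
               tolerance = 1e-12)
  # all random sample pairs of size <= 10 match the brute-force oracle
  set.seed(11)
  for (k in 1:30) {
    a <- round(rnorm(sample(2:10, 1)), 2)
    b <- round(rnorm(sample(2:10, 1)), 2)  # rounding forces some ties
    expect_equal(cramer_von_mises(a, b)$omega2,
                 brute_cvm_integral(a, b), tolerance = 1e-10)
  }
  expect_error(cramer_von_mises(1, c(1, 2)), "at least 2")
})

test_that("two-sample statistic and p-value match reference values", {
  # reference values from an independent implementation of the
  # asymptotic two-sample test
  c1 <- cramer_von_mises(c(1, 2, 3, 4, 5), c(1.5, 2.5, 3.5, 4.5, 5.5))
  expect_equal(c1$statistic, 0.05, tolerance = 1e-12)
  expect_equal(c1$pvalue, 0.9905271476587647, tolerance = 1e-9)
  c2 <- cramer_von_mises(c(0.3, 1.1, 2.2, 3.5, 4.1, 5.9, 6.2, 7.7),
                         c(2.4, 3.3, 4.8, 5.1, 6.6, 8.2, 9.0, 9.5))
  expect_equal(c2$statistic, 0.265625, tolerance = 1e-12)
  expect_equal(c2$pvalue, 0.17783586396802054, tolerance = 1e-9)
  # midrank tie handling
  c3 <- cramer_von_mises(c(1, 1, 2, 2, 3), c(1, 2, 2, 3, 3))
  expect_equal(c3$statistic, 0.07, tolerance = 1e-12)
  expect_equal(c3$pvalue, 0.9009381663977095, tolerance = 1e-9)
  # a strong shift is detected
  expect_lt(cramer_von_mises(rnorm(40), rnorm(40) + 3)$pvalue, 1e-6)
})

test_that("evaluation at zero theta is a fixed point", {
  ds <- tiny_dataset(n_molecules = 16, n_frames = 80, seed = 107)
  ds <- assign_splits(ds, 0.5, 3)
  basis <- fit_basis(ds, 2)
  ev <- evaluate_run(ds, basis, zero_params(2), n_boot = 200, seed = 1)
  expect_equal(ev$molecules$residual_pre, ev$molecules$residual_post)
  expect_equal(ev$cvm$omega2, rep(0, nrow(ev$cvm)))
  pre <- ev$stats[ev$stats$phase == "pre", c("split", "rmse", "mue")]
  post <- ev$stats[ev$stats$phase == "post", c("split", "rmse", "mue")]
  expect_equal(pre, post)
  expect_equal(ev$delta_rmse$delta_rmse, rep(0, nrow(ev$delta_rmse)))
})

test_that("a recovery run improves the test split detectably", {
  ds <- tiny_dataset(n_molecules = 30, n_frames = 300, seed = 109,
                     theta_sd = 0.5, atoms_min = 5, atoms_max = 12)
  ds <- assign_splits(ds, 0.6, 5)
  basis <- fit_basis(ds, 2)
  fit <- finetune(ds, basis, tiny_loss_config(300),
                  finetune_control(max_iter = 60))
  ev <- evaluate_run(ds, basis, fit$theta, n_boot = 400, seed = 2)
  st <- ev$stats
  rmse <- function(sp, ph) st$rmse[st$split == sp & st$phase == ph]
  expect_lt(rmse("test", "post"), rmse("test", "pre"))
  expect_gt(ev$cvm$omega2[ev$cvm$split == "train"], 0)
  # tidy/glance/autoplot interfaces
  expect_s3_class(tidy(ev), "tbl_df")
  expect_equal(nrow(glance(ev)), 1)
  expect_s3_class(autoplot(ev), "ggplot")
  # the report round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(ev$stats, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$rmse, ev$stats$rmse)
})

test_that("tiny splits are reported as missing with a warning", {
  # 7 molecules at 50% train: 3 train, 1 validate, 3 test
  ds <- tiny_dataset(n_molecules = 7, n_frames = 60, seed = 113)
  ds <- assign_splits(ds, 0.5, 1)
  basis <- fit_basis(ds, 2)
  expect_warning(
    ev <- evaluate_run(ds, basis, zero_params(2), n_boot = 50, seed = 1),
    "too few")
  expect_false("validate" %in% ev$stats$split)
})

test_that("reweighted estimates agree with the exact oracle", {
  ds <- tiny_dataset(n_molecules = 10, n_frames = 400, seed = 127,
                     theta_sd = 0.3)
  basis <- fit_basis(ds, 2)
  # theta = 0: exact agreement
  cc0 <- consistency_check(ds, basis, zero_params(2))
  expect_equal(cc0$rmse_reweight_vs_exact, 0)
  # small perturbations: deviations within the pooled estimator error
  tt <- true_params(ds)
  cc <- consistency_check(ds, basis, tt)
  expect_lt(cc$rmse_reweight_vs_exact, 3 * cc$pooled_se)
  # collapsing overlap inflates the deviation
  big <- ft_params(tt$theta_e * 8, tt$theta_s * 0)
  cc_big <- consistency_check(ds, basis, big)
  ok <- !is.na(cc_big$table$deviation)
  expect_gt(sqrt(mean(cc_big$table$deviation[ok]^2)),
            cc$rmse_reweight_vs_exact)
  expect_error(
    consistency_check(
      ct_dataset(dplyr::select(ds$molecules, -spec), beta = ds$beta,
                 m = ds$m),
      basis, tt),
    "ensemble")
})
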