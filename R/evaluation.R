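# Accuracy statistics with bootstrap confidence intervals, and the
# Cramer-von Mises criterion for pre/post-fit residual-distribution
# shift.

#' RMSE and MUE with bootstrap confidence intervals
#'
#' Root-mean-square error and mean unsigned error of a residual vector,
#' with nonparametric (percentile) bootstrap 95% intervals over
#' molecules. RMSE >= MUE always.
#'
#' @param residuals Numeric vector (>= 2 values).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed.
#' @return One-row tibble: `rmse`, `mue`, `rmse_lo`, `rmse_hi`,
#'   `mue_lo`, `mue_hi`, `n`.
#' @export
accuracy_stats <- function(residuals, n_boot = 1000, seed = 1L) {
  n <- length(residuals)
  if (n < 2L) abort("need at least 2 residuals")
  check_finite(residuals, "residuals")
  rmse <- sqrt(mean(residuals^2))
  mue <- mean(abs(residuals))
  boot <- withr::with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      r <- residuals[sample.int(n, n, replace = TRUE)]
      c(sqrt(mean(r^2)), mean(abs(r)))
    }, numeric(2)))
  })
  ci <- apply(boot, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  tibble(rmse = rmse, mue = mue,
         rmse_lo = ci[1, 1], rmse_hi = ci[2, 1],
         mue_lo = ci[1, 2], mue_hi = ci[2, 2], n = n)
}

# Limiting distribution of the Cramer-von Mises statistic (the
# Smirnov form), evaluated via the Bessel-K series; matches the
# asymptotic two-sample test.
cvm_limit_cdf <- function(x) {
  vapply_dbl(x, function(t) {
    if (t <= 0) return(0)
    if (t > 10) return(1)
    total <- 0
    for (k in 0:10) {
      z <- (4 * k + 1)^2 / (16 * t)
      if (z > 700) next
      coef <- gamma(k + 0.5) / (gamma(0.5) * factorial(k))
      # exp(-z) * besselK(z) computed with the scaled Bessel function
      total <- total + coef * sqrt(4 * k + 1) * exp(-2 * z) *
        besselK(z, 0.25, expon.scaled = TRUE)
    }
    min(1, total / (pi * sqrt(t)))
  })
}

#' Two-sample Cramer-von Mises criterion
#'
#' Measures the squared deviation between two empirical CDFs across
#' their entire range. Two quantities are returned: `omega2`, the
#' one-directional integral `int (F_a - F_b)^2 dF_b` (zero iff the
#' empirical CDFs coincide on the second sample's support), and the
#' symmetric two-sample rank statistic `statistic` (Anderson's T, with
#' midrank ties) whose asymptotic null distribution supplies `pvalue`.
#'
#' @param sample_a,sample_b Numeric vectors with at least 2 values each.
#' @return A list: `omega2`, `statistic`, `pvalue`, `n_a`, `n_b`.
#' @export
cramer_von_mises <- function(sample_a, sample_b) {
  n <- length(sample_a); m <- length(sample_b)
  if (n < 2L || m < 2L) abort("both samples need at least 2 values")
  check_finite(sample_a, "sample_a")
  check_finite(sample_b, "sample_b")
  fa <- stats::ecdf(sample_a)
  fb <- stats::ecdf(sample_b)
  omega2 <- mean((fa(sample_b) - fb(sample_b))^2)
  # Anderson's two-sample statistic on midranks of the pooled sample
  pooled <- c(sample_a, sample_b)
  rk <- rank(pooled, ties.method = "average")
  ra <- sort(rk[seq_len(n)])
  rb <- sort(rk[n + seq_len(m)])
  u <- n * sum((ra - seq_len(n))^2) + m * sum((rb - seq_len(m))^2)
  t_stat <- u / (n * m * (n + m)) - (4 * n * m - 1) / (6 * (n + m))
  # rescale the finite-sample statistic to the limiting distribution's
  # mean 1/6 and variance 1/45 (Anderson's moment correction)
  nn <- n + m
  et <- (1 + 1 / nn) / 6
  vt <- (nn + 1) * (4 * n * m * nn - 3 * (n^2 + m^2) - 2 * n * m) /
    (45 * nn^2 * 4 * n * m)
  t_adj <- (t_stat - et) / sqrt(45 * vt) + 1 / 6
  pvalue <- max(0, min(1, 1 - cvm_limit_cdf(t_adj)))
  list(omega2 = omega2, statistic = t_stat, pvalue = pvalue,
       n_a = n, n_b = m)
}

#' Evaluate a fitted perturbation against the baseline
#'
#' Per split, reweights every molecule at `theta` and at the zero
#' matrix, computes RMSE/MUE with bootstrap intervals for both, the
#' Cramer-von Mises shift between pre- and post-fit absolute-residual
#' distributions, and a paired-bootstrap 95% interval for the RMSE
#' change. Splits with fewer than 2 molecules are reported as `NA` with
#' a warning. At `theta = 0` evaluation is a fixed point: post equals
#' pre and every omega^2 is zero.
#'
#' @param dataset A split-assigned `ct_dataset`.
#' @param basis A `ct_basis`.
#' @param theta A `ct_params`.
#' @param beta Inverse thermal energy; defaults to the dataset's.
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return An object of class `ct_eval`: `stats` (split x phase
#'   accuracy tibble), `cvm` (per-split omega^2, statistic, p-value),
#'   `delta_rmse` (paired-bootstrap RMSE change intervals), `molecules`
#'   (per-molecule pre/post residual table).
#' @export
evaluate_run <- function(dataset, basis, theta, beta = NULL,
                         n_boot = 1000, seed = 1L) {
  beta <- beta %||% dataset$beta
  post <- reweight_dataset(dataset, basis, theta, beta)
  pre <- reweight_dataset(dataset, basis, zero_params(basis$r), beta)
  molecules <- tibble(
    molecule_id = post$molecule_id, split = post$split,
    residual_pre = pre$residual, residual_post = post$residual,
    dG_pert = post$dG_pert, ess = post$ess, n_frames = post$n_frames)
  splits <- intersect(SPLIT_LEVELS, unique(molecules$split))
  stats_rows <- list(); cvm_rows <- list(); drmse_rows <- list()
  for (sp in splits) {
    sub <- molecules[molecules$split == sp, ]
    if (nrow(sub) < 2L || anyNA(sub$residual_post)) {
      warn(sprintf("split \"%s\": too few molecules for statistics", sp))
      next
    }
    for (phase in c("pre", "post")) {
      res <- if (phase == "pre") sub$residual_pre else sub$residual_post
      stats_rows[[paste(sp, phase)]] <- dplyr::bind_cols(
        tibble(split = sp, phase = phase),
        accuracy_stats(res, n_boot, seed))
    }
    cv <- cramer_von_mises(abs(sub$residual_post), abs(sub$residual_pre))
    cvm_rows[[sp]] <- tibble(split = sp, omega2 = cv$omega2,
                             statistic = cv$statistic,
                             pvalue = cv$pvalue, n = nrow(sub))
    dr <- withr::with_seed(seed, {
      vapply_dbl(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(sub), nrow(sub), replace = TRUE)
        sqrt(mean(sub$residual_post[idx]^2)) -
          sqrt(mean(sub$residual_pre[idx]^2))
      })
    })
    drmse_rows[[sp]] <- tibble(
      split = sp,
      delta_rmse = sqrt(mean(sub$residual_post^2)) -
        sqrt(mean(sub$residual_pre^2)),
      lo = quantile(dr, 0.025, names = FALSE),
      hi = quantile(dr, 0.975, names = FALSE))
  }
  structure(
    list(stats = dplyr::bind_rows(stats_rows),
         cvm = dplyr::bind_rows(cvm_rows),
         delta_rmse = dplyr::bind_rows(drmse_rows),
         molecules = molecules),
    class = "ct_eval")
}

#' @export
print.ct_eval <- function(x, ...) {
  cat("<ct_eval>\n")
  print(x$stats, n = Inf)
  invisible(x)
}

#' @export
tidy.ct_eval <- function(x, ...) x$stats

#' @export
glance.ct_eval <- function(x, ...) {
  x$delta_rmse |>
    tidyr::pivot_wider(names_from = split,
                       values_from = c(delta_rmse, lo, hi))
}

#' Plot pre/post absolute-residual CDFs
#'
#' Empirical CDFs of absolute free-energy residuals per split, before
#' and after fine-tuning.
#'
#' @param object A `ct_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_eval <- function(object, ...) {
  long <- object$molecules |>
    tidyr::pivot_longer(c(residual_pre, residual_post),
                        names_to = "phase", values_to = "residual",
                        names_prefix = "residual_") |>
    dplyr::mutate(abs_residual = abs(residual))
  ggplot2::ggplot(long,
                  ggplot2::aes(abs_residual, colour = phase)) +
    ggplot2::stat_ecdf() +
    ggplot2::facet_wrap(~split) +
    ggplot2::labs(x = "|free energy residual| (kcal/mol)",
                  y = "empirical CDF") +
    ggplot2::theme_minimal()
}

#' Reweighted-vs-exact consistency check
#'
#' For synthetic datasets carrying Gaussian ensemble specifications,
#' compares each molecule's reweighted free energy at `theta` against
#' the closed-form perturbed free energy from the generator oracle (the
#' stand-in for re-simulating at the perturbed charges) and reports the
#' RMSE of the deviations.
#'
#' @inheritParams evaluate_run
#' @return List: `rmse_reweight_vs_exact`, `pooled_se` (closed-form
#'   pooled Zwanzig standard error), and a per-molecule `table` with
#'   reweighted, exact, deviation, ESS, and per-molecule standard
#'   error.
#' @export
consistency_check <- function(dataset, basis, theta, beta = NULL) {
  beta <- beta %||% dataset$beta
  if (!("spec" %in% names(dataset$molecules))) {
    abort("dataset carries no ensemble specifications")
  }
  rows <- purrr::map_dfr(seq_len(n_molecules(dataset)), function(i) {
    rec <- get_record(dataset, i)
    rw <- reweight_molecule(rec, basis, theta, beta)
    if (!rw$feasible) {
      return(tibble(molecule_id = rec$molecule_id, dG_reweight = NA_real_,
                    dG_exact = NA_real_, deviation = NA_real_,
                    ess = NA_real_, se_exact = NA_real_))
    }
    q_star <- perturbed_charges(rec, basis, theta)
    exact <- rec$dG_calc + exact_dg_pert(rec$spec, rec$q, q_star, beta)
    tibble(molecule_id = rec$molecule_id, dG_reweight = rw$dG_reweight,
           dG_exact = exact, deviation = rw$dG_reweight - exact,
           ess = rw$ess,
           se_exact = exact_zwanzig_stderr(rec$spec, rec$q, q_star,
                                           beta, nrow(rec$phi)))
  })
  list(
    rmse_reweight_vs_exact = sqrt(mean(rows$deviation^2, na.rm = TRUE)),
    pooled_se = sqrt(mean(rows$se_exact^2, na.rm = TRUE)),
    table = rows)
}
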