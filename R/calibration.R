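# ESS-threshold calibration: bootstrap the Zwanzig perturbation at a
# range of (effective) sample sizes and find where the upper error
# envelope drops below a reference uncertainty. Bootstrap size is
# equated with ESS on the grid, which is a good approximation for the
# near-uniform-weight ensembles the inclusion floor selects.

#' Bootstrap bias and spread of the Zwanzig perturbation
#'
#' Resamples `size` frames with replacement `n_boot` times, recomputes
#' the Zwanzig perturbation on each resample, and reports the bias of
#' the resampled mean relative to the full-sample estimate together with
#' the resampling standard deviation. Raw frames are resampled and the
#' perturbation energies recomputed at `theta`; deterministic given
#' `seed`.
#'
#' @param record Molecule record.
#' @param basis A `ct_basis`.
#' @param theta A `ct_params`.
#' @param beta Inverse thermal energy.
#' @param size Resample size, `2 <= size <= n_frames`.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @param weighted Resample frames with probability proportional to
#'   their importance weights at `theta` instead of uniformly
#'   (default `FALSE`: raw-frame resampling, with the perturbation
#'   energies recomputed at `theta` on each resample).
#' @return List with `bias`, `stdev`, `dg_full`.
#' @export
bootstrap_pert_error <- function(record, basis, theta, beta, size,
                                 n_boot = 200, seed = 1L,
                                 weighted = FALSE) {
  n_frames <- nrow(record$phi)
  if (size < 2 || size > n_frames) {
    abort(sprintf("`size` must lie in [2, %d]", n_frames))
  }
  q_star <- perturbed_charges(record, basis, theta)
  du <- delta_energies(record, q_star)
  dg_full <- zwanzig_dg(du, beta)
  prob <- if (weighted) {
    lw <- importance_weights(du, beta)
    exp(lw - logsumexp(lw))
  } else NULL
  boot <- withr::with_seed(seed, {
    vapply_dbl(seq_len(n_boot), function(b) {
      zwanzig_dg(du[sample.int(n_frames, size, replace = TRUE,
                               prob = prob)], beta)
    })
  })
  list(bias = mean(boot) - dg_full, stdev = sd(boot), dg_full = dg_full)
}

#' Calibrate the reliable-reweighting ESS threshold
#'
#' Restricts to molecules whose full-sample ESS at `theta` exceeds an
#' inclusion floor, evaluates the total bootstrap error
#' (|bias| + standard deviation) of the free-energy perturbation over a
#' grid of resample sizes, averages across molecules, and returns the
#' smallest grid size from which the upper 95% envelope (97.5th
#' percentile across molecules) stays at or below the supplied reference
#' error - the uncertainty of the baseline free-energy calculation.
#' When no grid point qualifies the threshold is `NA` with a warning.
#'
#' @param dataset A `ct_dataset`.
#' @param basis A `ct_basis`.
#' @param theta Perturbation parameters the calibration probes (the
#'   intended use is the final iterate of an unregularized fit).
#' @param beta Inverse thermal energy; defaults to the dataset's.
#' @param reference_error Reference uncertainty, kcal/mol (the headline
#'   use case feeds the mean baseline estimator uncertainty here).
#' @param ess_floor Full-sample ESS inclusion floor (default 2500).
#' @param ess_grid Ascending resample sizes; default 20 log-spaced
#'   values from 10 to the smallest frame count.
#' @param n_boot Bootstrap resamples per molecule and size.
#' @param seed Integer seed (curves are reproducible given it).
#' @return An object of class `ct_calibration`: `curve` (tibble with
#'   `ess`, `mean_total_error`, `upper95`), `threshold_ess`,
#'   `reference_error`, `molecule_ids` used.
#' @export
calibrate_threshold <- function(dataset, basis, theta, beta = NULL,
                                reference_error, ess_floor = 2500,
                                ess_grid = NULL, n_boot = 200,
                                seed = 1L) {
  beta <- beta %||% dataset$beta
  n_min <- min(vapply_dbl(dataset$molecules$phi, nrow))
  ess_grid <- ess_grid %||%
    unique(round(exp(seq(log(10), log(n_min), length.out = 20))))
  ess_grid <- sort(ess_grid)
  if (any(ess_grid < 2) || any(ess_grid > n_min)) {
    abort("`ess_grid` values must lie in [2, min n_frames]")
  }
  rw <- reweight_dataset(dataset, basis, theta, beta)
  keep <- which(rw$feasible & rw$ess >= ess_floor)
  if (length(keep) == 0L) {
    abort(sprintf("no molecule has full-sample ESS >= %g", ess_floor))
  }
  errs <- matrix(NA_real_, length(keep), length(ess_grid))
  for (a in seq_along(keep)) {
    rec <- get_record(dataset, keep[a])
    for (g in seq_along(ess_grid)) {
      be <- bootstrap_pert_error(rec, basis, theta, beta,
                                 size = ess_grid[g], n_boot = n_boot,
                                 seed = seed + 7919L * a + g)
      errs[a, g] <- abs(be$bias) + be$stdev
    }
  }
  curve <- tibble(
    ess = ess_grid,
    mean_total_error = colMeans(errs),
    upper95 = apply(errs, 2L, quantile, probs = 0.975, names = FALSE))
  ok <- curve$upper95 <= reference_error
  # smallest grid point from which the envelope stays below the
  # reference for all larger sizes
  idx <- NA_integer_
  for (g in rev(seq_along(ok))) {
    if (!ok[g]) break
    idx <- g
  }
  threshold <- if (is.na(idx)) {
    warn("upper 95% envelope never falls below the reference error")
    NA_real_
  } else {
    curve$ess[idx]
  }
  structure(
    list(curve = curve, threshold_ess = threshold,
         reference_error = reference_error,
         molecule_ids = rw$molecule_id[keep]),
    class = "ct_calibration")
}

#' @export
print.ct_calibration <- function(x, ...) {
  cat(sprintf(
    "<ct_calibration> %d molecules, %d grid points, threshold ESS: %s\n",
    length(x$molecule_ids), nrow(x$curve),
    if (is.na(x$threshold_ess)) "not found" else
      format(x$threshold_ess)))
  invisible(x)
}

#' @export
tidy.ct_calibration <- function(x, ...) x$curve

#' Plot a calibration curve
#'
#' Total bootstrap error of the free-energy perturbation against
#' (effective) sample size, with the upper 95% envelope, the reference
#' error (horizontal dashed line) and the detected threshold (vertical
#' dotted line).
#'
#' @param object A `ct_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_calibration <- function(object, ...) {
  p <- ggplot2::ggplot(object$curve, ggplot2::aes(ess, mean_total_error)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 0, ymax = upper95),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$reference_error,
                        linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "effective sample size",
                  y = "|bias| + bootstrap sd (kcal/mol)") +
    ggplot2::theme_minimal()
  if (!is.na(object$threshold_ess)) {
    p <- p + ggplot2::geom_vline(xintercept = object$threshold_ess,
                                 linetype = 3)
  }
  p
}
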