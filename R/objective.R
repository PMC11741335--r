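# ESS-regularized loss over the whole dataset, with an analytic
# gradient. The data term is the mean pseudo-Huber of training-split
# residuals; the regularization term sums a flat-to-quadratic penalty on
# every molecule's ESS (all splits by default), steering optimization
# away from parameter regions where reweighting becomes unreliable.

#' Loss configuration
#'
#' Tunable parameters of the ESS-regularized objective.
#'
#' @param delta Pseudo-Huber scale. In the default `loss_units = "kbt"`
#'   residuals are expressed in units of kBT before entering the loss and
#'   `delta = 1` means one thermal energy; with `loss_units = "kcal"`
#'   residuals stay in kcal/mol and `delta` is in kcal/mol.
#' @param k_reg Regularization stiffness (default 100). `k_reg = 0`
#'   disables regularization (the early-stopping monitor still runs).
#' @param a_onset ESS (samples) below which the quadratic penalty turns
#'   on (default 750). Must satisfy
#'   `ess_stop <= a_onset < min(n_frames)`.
#' @param ess_stop Early-stopping ESS threshold in samples (default 500):
#'   optimization halts once any molecule's ESS falls below it.
#' @param regularize_splits `"all"` (default; penalize every molecule's
#'   ESS, protecting prospective predictions on validate/test molecules)
#'   or `"train_only"`.
#' @param loss_units Units of the residual inside the pseudo-Huber,
#'   `"kbt"` (default) or `"kcal"`.
#' @param s_floor Hardness feasibility floor (default 1e-6).
#' @param normalize_ess Divide ESS and `a_onset` by each molecule's frame
#'   count inside the penalty, for datasets with heterogeneous frame
#'   counts (default `FALSE`: raw sample counts, under which the default
#'   stiffness acts as a near-hard constraint).
#' @param smooth_penalty Use a C-infinity squared-softplus penalty
#'   instead of the C^1 hinge-quadratic (default `FALSE`; the hinge is
#'   sufficient for quasi-Newton optimization).
#' @return A list of class `ct_loss_config`.
#' @export
loss_config <- function(delta = 1, k_reg = 100, a_onset = 750,
                        ess_stop = 500,
                        regularize_splits = c("all", "train_only"),
                        loss_units = c("kbt", "kcal"),
                        s_floor = 1e-6, normalize_ess = FALSE,
                        smooth_penalty = FALSE) {
  regularize_splits <- match.arg(regularize_splits)
  loss_units <- match.arg(loss_units)
  stopifnot(delta > 0, k_reg >= 0, a_onset > 0, ess_stop > 0)
  if (ess_stop > a_onset) {
    abort("`ess_stop` must not exceed `a_onset`")
  }
  structure(
    list(delta = delta, k_reg = k_reg, a_onset = a_onset,
         ess_stop = ess_stop, regularize_splits = regularize_splits,
         loss_units = loss_units, s_floor = s_floor,
         normalize_ess = normalize_ess, smooth_penalty = smooth_penalty),
    class = "ct_loss_config")
}

INFEASIBLE_LOSS <- 1e10

#' Pseudo-Huber loss
#'
#' `L_delta(x) = delta^2 (sqrt(1 + (x/delta)^2) - 1)`: smooth, even,
#' quadratic near zero and asymptotically linear with slope `delta`, so
#' large residuals (outliers) are not over-penalized the way a squared
#' loss would.
#'
#' @param x Residual(s).
#' @param delta Positive scale parameter.
#' @return Nonnegative value(s), same length as `x`.
#' @export
pseudo_huber <- function(x, delta) {
  stopifnot(delta > 0)
  delta^2 * (sqrt(1 + (x / delta)^2) - 1)
}

pseudo_huber_grad <- function(x, delta) {
  x / sqrt(1 + (x / delta)^2)
}

#' ESS regularization penalty
#'
#' Flat-to-quadratic penalty on a molecule's effective sample size:
#' zero for `ess >= a_onset` and `k_reg (a_onset - ess)^2` below it,
#' continuous with continuous first derivative at the onset. Penalizing
#' ESS values that fall below the onset keeps optimization inside the
#' trust region where reweighted free energies remain reliable.
#'
#' @param ess ESS value(s), each at least 1.
#' @param config A [loss_config()] (uses `k_reg`, `a_onset`,
#'   `smooth_penalty`).
#' @return Nonnegative penalty value(s).
#' @export
ess_penalty <- function(ess, config) {
  stopifnot(inherits(config, "ct_loss_config"))
  deficit <- config$a_onset - ess
  if (config$smooth_penalty) {
    sp <- ifelse(deficit > 30, deficit, log1p(exp(pmin(deficit, 30))))
    config$k_reg * sp^2
  } else {
    config$k_reg * pmax(deficit, 0)^2
  }
}

# d penalty / d ess
ess_penalty_grad <- function(ess, config) {
  deficit <- config$a_onset - ess
  if (config$smooth_penalty) {
    sp <- ifelse(deficit > 30, deficit, log1p(exp(pmin(deficit, 30))))
    sig <- 1 / (1 + exp(-deficit))
    -2 * config$k_reg * sp * sig
  } else {
    -2 * config$k_reg * pmax(deficit, 0)
  }
}

# Precompute everything theta-independent once per (dataset, basis):
# projected embeddings, baseline residuals, per-molecule arrays.
compile_problem <- function(dataset, basis, config) {
  stopifnot(inherits(dataset, "ct_dataset"), inherits(basis, "ct_basis"))
  mol <- dataset$molecules
  n_frames <- vapply_dbl(mol$phi, nrow)
  if (config$a_onset >= min(n_frames)) {
    abort(sprintf(
      "`a_onset` (%g) must be below the smallest frame count (%d)",
      config$a_onset, min(n_frames)))
  }
  mols <- lapply(seq_len(nrow(mol)), function(i) {
    list(
      molecule_id = mol$molecule_id[[i]],
      h_hat = project(basis, mol$embeddings[[i]]),
      e = mol$e[[i]], s = mol$s[[i]], q = mol$q[[i]], Q = mol$Q[[i]],
      phi = mol$phi[[i]], n_frames = n_frames[[i]],
      resid0 = mol$dG_expt[[i]] - mol$dG_calc[[i]],
      is_train = mol$split[[i]] == "train",
      regularized = config$regularize_splits == "all" ||
        mol$split[[i]] == "train")
  })
  n_train <- sum(vapply(mols, function(x) x$is_train, logical(1)))
  if (n_train == 0L) abort("dataset has no training molecules")
  list(mols = mols, n_train = n_train, beta = dataset$beta,
       r = basis$r, config = config)
}

# Full evaluation at theta: loss, components, optionally gradient.
# Returns a sentinel loss with feasible = FALSE when any molecule's
# perturbed hardness crosses the floor.
eval_objective <- function(prob, theta, need_grad = TRUE) {
  cfg <- prob$config
  beta <- prob$beta
  units <- if (cfg$loss_units == "kbt") beta else 1
  grad_e <- numeric(prob$r)
  grad_s <- numeric(prob$r)
  data_loss <- 0
  reg_loss <- 0
  per <- vector("list", length(prob$mols))
  for (j in seq_along(prob$mols)) {
    mlc <- prob$mols[[j]]
    e_star <- mlc$e + drop(mlc$h_hat %*% theta$theta_e)
    s_star <- mlc$s + drop(mlc$h_hat %*% theta$theta_s)
    if (any(s_star <= cfg$s_floor)) {
      return(list(loss = INFEASIBLE_LOSS, feasible = FALSE,
                  infeasible_molecule = mlc$molecule_id))
    }
    q_star <- qeq_charges(e_star, s_star, mlc$Q)
    du <- drop(mlc$phi %*% (q_star - mlc$q))
    a <- -beta * du
    m_shift <- max(a)
    w <- exp(a - m_shift)
    s1 <- sum(w); s2 <- sum(w^2)
    ess <- s1^2 / s2
    n <- mlc$n_frames
    dg_pert <- -(m_shift + log(s1 / n)) / beta
    resid <- mlc$resid0 - dg_pert
    # normalize_ess: compare ess/n against a_onset/n; same penalty shape
    # on the rescaled deficit.
    if (cfg$normalize_ess) {
      pen <- cfg$k_reg * pmax(cfg$a_onset / n - ess / n, 0)^2
      dpen_dess <- -2 * cfg$k_reg * pmax(cfg$a_onset / n - ess / n, 0) / n
    } else {
      pen <- ess_penalty(ess, cfg)
      dpen_dess <- ess_penalty_grad(ess, cfg)
    }
    if (!mlc$regularized) {
      pen <- 0; dpen_dess <- 0
    }
    reg_loss <- reg_loss + pen
    x <- units * resid
    data_contrib <- if (mlc$is_train) {
      pseudo_huber(x, cfg$delta) / prob$n_train
    } else 0
    data_loss <- data_loss + data_contrib
    if (need_grad) {
      wbar <- w / s1
      # dG/dq*  (through dU -> weights)
      phibar <- drop(crossprod(mlc$phi, wbar))
      v_total <- numeric(length(q_star))
      if (mlc$is_train) {
        coef <- pseudo_huber_grad(x, cfg$delta) * units *
          (-1) / prob$n_train
        v_total <- v_total + coef * phibar
      }
      if (dpen_dess != 0) {
        cc <- s1 / s2
        g_t <- -2 * beta * cc * w * (1 - cc * w)
        psi <- drop(crossprod(mlc$phi, g_t))
        v_total <- v_total + dpen_dess * psi
      }
      if (any(v_total != 0)) {
        jtv <- qeq_jacobian_tv(e_star, s_star, mlc$Q, v_total)
        grad_e <- grad_e + drop(crossprod(mlc$h_hat, jtv$e))
        grad_s <- grad_s + drop(crossprod(mlc$h_hat, jtv$s))
      }
    }
    per[[j]] <- c(ess = ess, dG_pert = dg_pert, residual = resid,
                  penalty = pen, data_contrib = data_contrib)
  }
  per_mol <- as_tibble(do.call(rbind, per))
  per_mol <- dplyr::mutate(
    per_mol,
    molecule_id = vapply(prob$mols, function(x) x$molecule_id,
                         character(1)),
    split = ifelse(vapply(prob$mols, function(x) x$is_train, logical(1)),
                   "train", "other"),
    .before = 1)
  list(loss = data_loss + reg_loss, data_loss = data_loss,
       reg_loss = reg_loss, feasible = TRUE,
       gradient = if (need_grad) rbind(e = grad_e, s = grad_s) else NULL,
       min_ess = min(per_mol$ess),
       argmin_molecule = per_mol$molecule_id[which.min(per_mol$ess)],
       max_abs_dg_pert = max(abs(per_mol$dG_pert)),
       per_molecule = per_mol)
}

#' ESS-regularized total loss
#'
#' `loss = sum_j RegESS(ESS_j) + (1/N_train) sum_{i in train}
#' L_delta(residual_i)`: the ESS penalty runs over all molecules (by
#' default, all splits), the pseudo-Huber data term over training
#' molecules only. Differentiable in `theta` wherever the perturbation
#' is feasible; infeasible points return a large finite sentinel loss
#' with an `infeasible` flag.
#'
#' @param dataset A split-assigned `ct_dataset`.
#' @param basis A `ct_basis`.
#' @param theta A `ct_params` with rank matching the basis.
#' @param config A [loss_config()].
#' @return List with `loss`, `data_loss`, `reg_loss`, `feasible`,
#'   `min_ess`, and a `per_molecule` tibble.
#' @export
total_loss <- function(dataset, basis, theta, config = loss_config()) {
  prob <- compile_problem(dataset, basis, config)
  out <- eval_objective(prob, theta, need_grad = FALSE)
  out$gradient <- NULL
  out
}

#' Gradient of the total loss
#'
#' Analytic gradient of [total_loss()] with respect to the 2 x r
#' parameter matrix, chained through the QEq Jacobian, the per-frame
#' energies, and the Zwanzig/ESS weight functions. Matches central
#' finite differences to relative tolerance 1e-5 on feasible points.
#'
#' @inheritParams total_loss
#' @return A `2 x r` matrix with rows `e` and `s`.
#' @export
loss_gradient <- function(dataset, basis, theta, config = loss_config()) {
  prob <- compile_problem(dataset, basis, config)
  out <- eval_objective(prob, theta, need_grad = TRUE)
  if (!out$feasible) {
    abort(sprintf("infeasible point (molecule \"%s\")",
                  out$infeasible_molecule))
  }
  out$gradient
}
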