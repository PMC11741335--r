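# Quasi-Newton (BFGS, inverse-Hessian update) minimization of the
# ESS-regularized loss with a strong-Wolfe line search, ESS-monitored
# early stopping on accepted iterates, and a full per-iteration trace.
# Base optim() cannot monitor per-iterate ESS or return the last
# feasible iterate, which is why the loop lives here; optim() remains an
# independent cross-check in the tests.

#' Optimizer control settings
#'
#' @param max_iter Maximum accepted iterations (default 500).
#' @param grad_tol Stop when the max-norm of the gradient falls below
#'   this (default 1e-6).
#' @param c1,c2 Strong-Wolfe sufficient-decrease and curvature constants.
#' @param step_init Initial trial step length.
#' @param verbose Print per-iteration progress.
#' @return List of class `ct_control`.
#' @export
finetune_control <- function(max_iter = 500, grad_tol = 1e-6,
                             c1 = 1e-4, c2 = 0.9, step_init = 1,
                             verbose = FALSE) {
  stopifnot(max_iter >= 1, grad_tol > 0, 0 < c1, c1 < c2, c2 < 1)
  structure(list(max_iter = max_iter, grad_tol = grad_tol, c1 = c1,
                 c2 = c2, step_init = step_init, verbose = verbose),
            class = "ct_control")
}

vec_to_params <- function(x, r) {
  ft_params(x[seq_len(r)], x[r + seq_len(r)])
}

# Strong-Wolfe line search (bracket + zoom). `f(x, need_grad)` returns
# list(loss, gradient, feasible, ...); infeasible points count as +Inf
# and are never accepted. The gradient is only computed once a trial
# point passes the sufficient-decrease test (points that fail it do not
# need a slope). Returns NULL when no acceptable step exists.
wolfe_search <- function(f, x0, f0, g0, p, control) {
  phi0 <- f0
  dphi0 <- sum(g0 * p)
  if (dphi0 >= 0) return(NULL)
  c1 <- control$c1; c2 <- control$c2
  armijo <- function(alpha, loss) loss <= phi0 + c1 * alpha * dphi0
  eval_at <- function(alpha, need_grad) {
    out <- f(x0 + alpha * p, need_grad)
    out$alpha <- alpha
    if (!out$feasible) {
      out$loss <- Inf
      out$dphi <- NA_real_
    } else if (need_grad) {
      out$dphi <- sum(c(out$gradient["e", ], out$gradient["s", ]) * p)
    }
    out
  }
  with_grad <- function(tr) {
    if (!is.null(tr$gradient)) return(tr)
    eval_at(tr$alpha, TRUE)
  }
  zoom <- function(lo, hi, flo) {
    for (k in 1:40) {
      alpha <- (lo$alpha + hi$alpha) / 2
      tr <- eval_at(alpha, FALSE)
      if (!is.finite(tr$loss) || !armijo(alpha, tr$loss) ||
          tr$loss >= flo$loss) {
        hi <- tr
      } else {
        tr <- with_grad(tr)
        if (abs(tr$dphi) <= -c2 * dphi0) return(tr)
        if (tr$dphi * (hi$alpha - lo$alpha) >= 0) hi <- lo
        lo <- tr; flo <- tr
      }
      if (abs(hi$alpha - lo$alpha) < 1e-14) break
    }
    if (is.finite(flo$loss) && flo$loss < phi0) with_grad(flo) else NULL
  }
  prev <- list(alpha = 0, loss = phi0, dphi = dphi0, gradient = TRUE)
  alpha <- control$step_init
  for (k in 1:15) {
    tr <- eval_at(alpha, FALSE)
    if (!is.finite(tr$loss) || !armijo(alpha, tr$loss) ||
        (k > 1 && tr$loss >= prev$loss)) {
      return(zoom(prev, tr, prev))
    }
    tr <- with_grad(tr)
    if (abs(tr$dphi) <= -c2 * dphi0) return(tr)
    if (tr$dphi >= 0) return(zoom(tr, prev, tr))
    prev <- tr
    alpha <- alpha * 2
  }
  NULL
}

#' Fine-tune perturbation parameters
#'
#' Minimizes the ESS-regularized loss by BFGS starting from the zero
#' parameter matrix. After every accepted iterate the smallest
#' per-molecule ESS is checked; if it falls below `config$ess_stop` the
#' run halts with `stop_reason = "early_stop_ess"` and returns the last
#' iterate whose minimum ESS satisfied the threshold, so the returned
#' parameters always lie inside the reweighting trust region.
#' Otherwise the run ends at the gradient tolerance (`"converged"`), a
#' stalled line search (`"converged"`), or `"max_iter"`. Deterministic
#' given its inputs.
#'
#' @param dataset A split-assigned `ct_dataset`.
#' @param basis A `ct_basis`.
#' @param config A [loss_config()].
#' @param control A [finetune_control()].
#' @return An object of class `ct_fit`: `theta` (a `ct_params`),
#'   `trace` (per-iteration tibble with loss components, min-ESS and its
#'   molecule, the largest |dG_pert|, the parameter norm, and the theta
#'   snapshot), `stop_reason`, `iterations`, plus the evaluation of the
#'   returned iterate.
#' @seealso [tidy.ct_fit()], [glance.ct_fit()], [autoplot.ct_fit()]
#' @export
finetune <- function(dataset, basis, config = loss_config(),
                     control = finetune_control()) {
  prob <- compile_problem(dataset, basis, config)
  r <- prob$r
  f <- function(x, need_grad = TRUE) {
    eval_objective(prob, vec_to_params(x, r), need_grad)
  }
  x <- numeric(2 * r)
  cur <- f(x)
  if (!cur$feasible || !is.finite(cur$loss)) {
    abort("loss is not finite at the zero parameter matrix")
  }
  trace_rows <- list()
  push_trace <- function(iter, ev, x) {
    trace_rows[[length(trace_rows) + 1L]] <<- tibble(
      iteration = iter, loss = ev$loss, data_loss = ev$data_loss,
      reg_loss = ev$reg_loss, min_ess = ev$min_ess,
      argmin_molecule = ev$argmin_molecule,
      max_abs_dg_pert = ev$max_abs_dg_pert,
      theta_norm = sqrt(sum(x^2)),
      grad_norm = max(abs(ev$gradient)),
      theta = list(vec_to_params(x, r)))
  }
  push_trace(0L, cur, x)
  last_ok <- list(x = x, ev = cur, iter = 0L)
  stop_reason <- "max_iter"
  B <- diag(2 * r)
  iter <- 0L
  while (iter < control$max_iter) {
    # gradient vector layout matches x = c(theta_e, theta_s)
    g <- c(cur$gradient["e", ], cur$gradient["s", ])
    if (max(abs(g)) <= control$grad_tol) {
      stop_reason <- "converged"
      break
    }
    p <- -drop(B %*% g)
    ls <- wolfe_search(f, x, cur$loss, g, p, control)
    if (is.null(ls)) {
      stop_reason <- "converged"
      break
    }
    iter <- iter + 1L
    x_new <- x + ls$alpha * p
    g_new <- c(ls$gradient["e", ], ls$gradient["s", ])
    s_vec <- x_new - x
    y_vec <- g_new - g
    sy <- sum(s_vec * y_vec)
    if (sy > 1e-12 * sqrt(sum(s_vec^2) * sum(y_vec^2))) {
      rho <- 1 / sy
      I <- diag(2 * r)
      V <- I - rho * outer(s_vec, y_vec)
      B <- V %*% B %*% t(V) + rho * outer(s_vec, s_vec)
    }
    x <- x_new
    cur <- ls
    push_trace(iter, cur, x)
    if (control$verbose) {
      cat(sprintf("iter %3d  loss %.6g  min ESS %.1f\n",
                  iter, cur$loss, cur$min_ess))
    }
    if (cur$min_ess < config$ess_stop) {
      stop_reason <- "early_stop_ess"
      break
    }
    last_ok <- list(x = x, ev = cur, iter = iter)
  }
  if (stop_reason != "early_stop_ess") last_ok <- list(x = x, ev = cur,
                                                       iter = iter)
  trace <- dplyr::bind_rows(trace_rows)
  structure(
    list(theta = vec_to_params(last_ok$x, r), trace = trace,
         stop_reason = stop_reason, iterations = iter,
         returned_iteration = last_ok$iter, final = last_ok$ev,
         config = config, control = control, r = r),
    class = "ct_fit")
}

#' @export
print.ct_fit <- function(x, ...) {
  cat(sprintf(
    "<ct_fit> rank %d, %d iterations, stop: %s\n", x$r, x$iterations,
    x$stop_reason))
  cat(sprintf(
    "  loss %.6g (data %.6g, reg %.6g), min ESS %.1f, |theta| %.4g\n",
    x$final$loss, x$final$data_loss, x$final$reg_loss, x$final$min_ess,
    params_norm(x$theta)))
  invisible(x)
}

#' Tidy a fitted fine-tuning model
#'
#' One row per parameter: the perturbation coefficient of each principal
#' component for the electronegativity (`e`) and hardness (`s`) rows.
#'
#' @param x A `ct_fit`.
#' @param ... Unused.
#' @return A tibble with `component`, `pc`, `estimate`.
#' @export
tidy.ct_fit <- function(x, ...) {
  tibble(component = rep(c("e", "s"), each = x$r),
         pc = rep(seq_len(x$r), 2L),
         estimate = c(x$theta$theta_e, x$theta$theta_s))
}

#' One-row summary of a fitted fine-tuning model
#'
#' @param x A `ct_fit`.
#' @param ... Unused.
#' @return A one-row tibble: iterations, final loss and its components,
#'   minimum ESS, parameter norm, stop reason.
#' @export
glance.ct_fit <- function(x, ...) {
  tibble(rank = x$r, iterations = x$iterations,
         loss = x$final$loss, data_loss = x$final$data_loss,
         reg_loss = x$final$reg_loss, min_ess = x$final$min_ess,
         theta_norm = params_norm(x$theta),
         stop_reason = x$stop_reason)
}

#' Plot an optimization trace
#'
#' Two panels against iteration: total loss, and the smallest
#' per-molecule ESS with the early-stopping threshold drawn as a dashed
#' line.
#'
#' @param object A `ct_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ct_fit <- function(object, ...) {
  tr <- object$trace |>
    dplyr::select(iteration, loss, min_ess) |>
    tidyr::pivot_longer(c(loss, min_ess), names_to = "quantity")
  thresh <- tibble(quantity = "min_ess", y = object$config$ess_stop)
  ggplot2::ggplot(tr, ggplot2::aes(iteration, value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(data = thresh,
                        ggplot2::aes(yintercept = y), linetype = 2) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "BFGS iteration", y = NULL) +
    ggplot2::theme_minimal()
}
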