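# Laplace-approximated marginal likelihood for grouped nonlinear models with
# a small number (q = 1 or 2) of independent Normal random effects per group.
#
# The marginal likelihood of group i is
#   L_i = integral exp(-condnll_i(eta)) prod_k dnorm(eta_k; 0, omega_k) deta,
# approximated by Laplace's method at the penalised mode eta_hat:
#   -log L_i ~= g_i(eta_hat) - (q/2) log(2 pi) + (1/2) log det H_i,
# where g_i = condnll_i + sum_k eta_k^2/(2 omega_k^2) + sum_k log(omega_k
# sqrt(2 pi)) and H_i is the Hessian of g_i at the mode.
#
# The inner optimisation is a damped Newton iteration run simultaneously for
# all groups: `cond_fn` evaluates the conditional data negative log-likelihood
# for every group at once (a G-vector), so each derivative evaluation is one
# vectorised pass over the whole dataset. Gradients and Hessians are central
# finite differences in the q inner coordinates.

.penalised_nll <- function(eta, omega, cond_fn) {
  pen <- sweep(eta^2, 2, 2 * omega^2, "/")
  cond_fn(eta) + rowSums(pen) + sum(log(omega)) + ncol(eta) * 0.5 * log(2 * pi)
}

.fd_grad_hess <- function(eta, omega, cond_fn, h) {
  G <- nrow(eta); q <- ncol(eta)
  g0 <- .penalised_nll(eta, omega, cond_fn)
  grad <- matrix(0, G, q)
  H <- array(0, c(G, q, q))
  for (k in seq_len(q)) {
    ep <- eta; ep[, k] <- ep[, k] + h
    em <- eta; em[, k] <- em[, k] - h
    gp <- .penalised_nll(ep, omega, cond_fn)
    gm <- .penalised_nll(em, omega, cond_fn)
    grad[, k] <- (gp - gm) / (2 * h)
    H[, k, k] <- (gp - 2 * g0 + gm) / h^2
  }
  if (q > 1) {
    for (k in seq_len(q - 1)) for (l in seq((k + 1), q)) {
      epp <- eta; epp[, k] <- epp[, k] + h; epp[, l] <- epp[, l] + h
      epm <- eta; epm[, k] <- epm[, k] + h; epm[, l] <- epm[, l] - h
      emp <- eta; emp[, k] <- emp[, k] - h; emp[, l] <- emp[, l] + h
      emm <- eta; emm[, k] <- emm[, k] - h; emm[, l] <- emm[, l] - h
      H[, k, l] <- H[, l, k] <-
        (.penalised_nll(epp, omega, cond_fn) - .penalised_nll(epm, omega, cond_fn) -
         .penalised_nll(emp, omega, cond_fn) + .penalised_nll(emm, omega, cond_fn)) /
        (4 * h^2)
    }
  }
  list(g = g0, grad = grad, H = H)
}

# Newton step for each group with a positive-definiteness ridge and a step
# cap (random effects live on the log scale, so steps beyond ~2 are never
# useful and indefinite-Hessian groups would otherwise explode); returns the
# G x q step matrix and the per-group log-determinant of the (ridged) Hessian.
.newton_step <- function(grad, H, omega, cap = 2) {
  G <- nrow(grad); q <- ncol(grad)
  floor_eig <- 1e-2 * max(1 / omega^2)
  if (q == 1L) {
    h11 <- pmax(H[, 1, 1], floor_eig)
    step <- matrix(-grad[, 1] / h11, ncol = 1)
  } else {
    h11 <- H[, 1, 1]; h22 <- H[, 2, 2]; h12 <- H[, 1, 2]
    # eigenvalue floor via trace/determinant
    tr <- h11 + h22
    dt <- h11 * h22 - h12^2
    emin <- (tr - sqrt(pmax(tr^2 - 4 * dt, 0))) / 2
    ridge <- pmax(floor_eig - emin, 0)
    h11 <- h11 + ridge; h22 <- h22 + ridge
    dt <- h11 * h22 - h12^2
    step <- cbind(-(h22 * grad[, 1] - h12 * grad[, 2]) / dt,
                  -(h11 * grad[, 2] - h12 * grad[, 1]) / dt)
  }
  step[!is.finite(step)] <- 0
  biggest <- apply(abs(step), 1, max)
  shrink <- pmin(1, cap / pmax(biggest, 1e-12))
  step <- step * shrink
  logdet <- if (q == 1L) log(pmax(h11, 1e-300)) else log(pmax(dt, 1e-300))
  list(step = step, logdet = logdet)
}

# Add the Normal-prior terms to analytic data-part derivatives.
.add_prior <- function(d, eta, omega) {
  q <- ncol(eta)
  pen <- sweep(eta^2, 2, 2 * omega^2, "/")
  d$g <- d$g + rowSums(pen) + sum(log(omega)) + q * 0.5 * log(2 * pi)
  d$grad <- d$grad + sweep(eta, 2, omega^2, "/")
  for (k in seq_len(q)) d$H[, k, k] <- d$H[, k, k] + 1 / omega[k]^2
  d
}

# Run the vectorised inner Newton iteration to the penalised modes and return
# the Laplace negative marginal log-likelihood summed over groups. If
# `deriv_fn` is supplied it must return the analytic data-part value,
# gradient and Hessian (list(g, grad, H)); otherwise central finite
# differences with step `fd_step` are used.
.laplace_nll <- function(eta0, omega, cond_fn, inner_tol = 1e-6,
                         inner_max_iter = 50L, fd_step = 1e-4,
                         deriv_fn = NULL) {
  eta <- eta0
  g <- .penalised_nll(eta, omega, cond_fn)
  if (any(!is.finite(g))) {
    eta[] <- 0
    g <- .penalised_nll(eta, omega, cond_fn)
    if (any(!is.finite(g))) return(list(nll = Inf, eta = eta, converged = FALSE))
  }
  get_gh <- function(eta) {
    if (is.null(deriv_fn)) .fd_grad_hess(eta, omega, cond_fn, fd_step)
    else .add_prior(deriv_fn(eta), eta, omega)
  }
  d <- NULL
  converged <- FALSE
  for (it in seq_len(inner_max_iter)) {
    d <- get_gh(eta)
    if (max(abs(d$grad)) < inner_tol) { converged <- TRUE; break }
    st <- .newton_step(d$grad, d$H, omega)
    s <- rep(1, nrow(eta))
    active <- rep(TRUE, nrow(eta))
    for (ls in 1:20) {
      cand <- eta + st$step * s
      gc <- .penalised_nll(cand, omega, cond_fn)
      better <- is.finite(gc) & (gc <= d$g + 1e-12)
      take <- active & better
      eta[take, ] <- cand[take, , drop = FALSE]
      g[take] <- gc[take]
      active <- active & !better
      if (!any(active)) break
      s[active] <- s[active] / 2
    }
    if (all(abs(st$step * s) < 1e-12)) { converged <- TRUE; break }
  }
  if (is.null(d) || !converged) d <- get_gh(eta)
  st <- .newton_step(d$grad, d$H, omega)
  q <- ncol(eta)
  nll_i <- d$g - q / 2 * log(2 * pi) + 0.5 * st$logdet
  list(nll = sum(nll_i), nll_by_group = nll_i, eta = eta,
       converged = converged || max(abs(d$grad)) < 1e-3)
}

# Quasi-Newton outer optimisation with bounded restarts: nlminb occasionally
# reports false convergence on badly conditioned Laplace surfaces (e.g. the
# near-noise-free limit); restarting from the stall point resumes progress.
.outer_optim <- function(par, obj, lower, control) {
  ctl <- list(iter.max = control$max_iter, eval.max = 4 * control$max_iter,
              rel.tol = control$rel_tol, x.tol = control$x_tol)
  opt <- stats::nlminb(par, obj, lower = lower, control = ctl)
  pass <- 1L
  while (opt$convergence != 0 && pass < 4L) {
    prev <- opt$objective
    opt2 <- stats::nlminb(opt$par, obj, lower = lower, control = ctl)
    pass <- pass + 1L
    if (!(opt2$objective < prev - 1e-8 * (1 + abs(prev)))) {
      if (opt2$objective <= prev) opt <- opt2
      break
    }
    opt <- opt2
  }
  opt
}

#' Control parameters for the NLME fitters
#'
#' @param rel_tol Relative objective tolerance of the outer quasi-Newton
#'   optimisation.
#' @param x_tol Relative parameter-change tolerance of the outer optimisation.
#' @param max_iter Maximum outer iterations.
#' @param inner_tol Gradient tolerance of the inner (random-effect mode)
#'   Newton iteration.
#' @param inner_max_iter Maximum inner Newton iterations per objective
#'   evaluation (warm-started, so usually 1-3 are used).
#' @param fd_step Central finite-difference step for inner derivatives.
#' @param omega_min Lower bound for random-effect SDs.
#' @return List of class `"fit_control"`.
#' @export
fit_control <- function(rel_tol = 1e-8, x_tol = 1e-6, max_iter = 500L,
                        inner_tol = 1e-8, inner_max_iter = 100L,
                        fd_step = 1e-4, omega_min = 1e-6) {
  structure(list(rel_tol = rel_tol, x_tol = x_tol, max_iter = max_iter,
                 inner_tol = inner_tol, inner_max_iter = inner_max_iter,
                 fd_step = fd_step, omega_min = omega_min),
            class = "fit_control")
}
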