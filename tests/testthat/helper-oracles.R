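# Independent numerical oracles used by the tests.

# Stiff-ODE solution of the two-compartment + forcing-function cage system.
ode_oracle <- function(p, cg, dose, times) {
  k10 <- p$CL / p$V
  rhs <- function(t, y, parms) {
    list(c(-(k10 + p$k12) * y[1] + p$k21 * y[2],
           p$k12 * y[1] - p$k21 * y[2],
           cg$k13 * y[1] - cg$k31 * y[3]))
  }
  out <- deSolve::lsoda(c(dose / p$V, 0, 0), times = c(0, times), func = rhs,
                        rtol = 1e-11, atol = 1e-13)
  list(plasma = out[-1, 2], cage = out[-1, 4])
}

# Gauss-Hermite rule (weight exp(-x^2)) via the Golub-Welsch eigen method.
gh_rule <- function(n) {
  J <- matrix(0, n, n)
  off <- sqrt(seq_len(n - 1) / 2)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Adaptive Gauss-Hermite negative marginal log-likelihood for a single group
# with one random effect: integrates exp(-cond_nll(eta)) * dnorm(eta, 0, omega).
agh_nll_1d <- function(cond_nll, omega, n_nodes = 9) {
  g <- function(e) cond_nll(e) + e^2 / (2 * omega^2) + log(omega) + 0.5 * log(2 * pi)
  opt <- stats::nlminb(0, g)
  mode <- opt$par
  h <- 1e-4
  curv <- (g(mode + h) - 2 * g(mode) + g(mode - h)) / h^2
  sigma <- 1 / sqrt(max(curv, 1e-12))
  rule <- gh_rule(n_nodes)
  gi <- vapply(mode + sqrt(2) * sigma * rule$x, g, numeric(1))
  g0 <- min(gi)
  -(log(sqrt(2) * sigma) - g0 +
      log(sum(rule$w * exp(g0 - gi + rule$x^2))))
}
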