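# Sequential NLME stage 1: population two-compartment plasma model.

# Internal: index structures for the plasma data.
.plasma_struct <- function(records, dose) {
  pl <- records[records$matrix == "plasma" & !records$below_dose_time &
                  records$time_h > 0, , drop = FALSE]
  if (nrow(pl) == 0) stop("no post-dose plasma records", call. = FALSE)
  sheep <- sort(unique(pl$sheep_id))
  gi <- match(pl$sheep_id, sheep)
  skey <- paste(pl$sheep_id, pl$period)
  us <- !duplicated(skey)
  series <- data.frame(key = skey[us], sheep = gi[us],
                       carr = as.numeric(pl$carr_sheep[us]))
  si <- match(skey, series$key)
  list(sheep = sheep, G = length(sheep), series = series,
       si = si, gobs = gi, t = pl$time_h, y = pl$conc_ug_ml,
       n_obs = nrow(pl), dose = dose, records = pl)
}

# Conditional data NLL per sheep, vectorised over all observations.
# theta: lV, lCL, lk12, lk21, b12, b21, lb (b12/b21 may be fixed at 0).
.plasma_cond_fn <- function(st, theta) {
  lV <- theta[["lV"]]; lCL <- theta[["lCL"]]
  k12_s <- exp(theta[["lk12"]] + theta[["b12"]] * st$series$carr)
  k21_s <- exp(theta[["lk21"]] + theta[["b21"]] * st$series$carr)
  b <- exp(theta[["lb"]])
  shp <- st$series$sheep
  function(eta) {
    V_s <- exp(lV + eta[shp, 1])
    CL_s <- exp(lCL + eta[shp, 2])
    k10 <- CL_s / V_s
    ssum <- k10 + k12_s + k21_s
    sq <- sqrt(ssum^2 - 4 * k10 * k21_s)
    lf <- (ssum + sq) / 2
    ls <- (ssum - sq) / 2
    c0 <- st$dose / V_s
    cf <- c0 * (lf - k21_s) / sq
    cs <- c0 * (k21_s - ls) / sq
    f <- cf[st$si] * exp(-lf[st$si] * st$t) + cs[st$si] * exp(-ls[st$si] * st$t)
    f <- pmax(f, 1e-300)
    nll <- log(b) + log(f) + (st$y - f)^2 / (2 * b^2 * f^2) + 0.5 * log(2 * pi)
    as.vector(rowsum(nll, st$gobs))
  }
}

.plasma_theta_names <- c("lV", "lCL", "lk12", "lk21", "b12", "b21",
                         "lomega_V", "lomega_CL", "lb")

# Crude data-driven starting values.
.plasma_start <- function(st) {
  first_t <- min(st$t)
  c0 <- mean(st$y[st$t == first_t])
  V0 <- st$dose / max(c0, 1e-6)
  late <- st$t >= stats::quantile(st$t, 0.6) & st$y > 0
  lz <- tryCatch(-unname(stats::coef(stats::lm(log(st$y[late]) ~ st$t[late]))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(lz) || lz <= 0) lz <- 0.05
  c(lV = log(V0), lCL = log(V0 * lz), lk12 = log(0.1), lk21 = log(0.1),
    b12 = 0, b21 = 0, lomega_V = log(0.3), lomega_CL = log(0.3), lb = log(0.2))
}

#' Fit the population plasma model (NLME, Laplace)
#'
#' Fits the two-compartment IV-bolus model to the plasma records by maximising
#' the Laplace-approximated marginal likelihood over the population typical
#' values (V, CL, k12, k21), the carrageenan-in-sheep log-linear effects on
#' k12 and k21, the per-sheep lognormal random-effect SDs on V and CL, and the
#' proportional residual error coefficient. Positivity is enforced by
#' optimising on the log scale; standard errors come from a numerical Hessian
#' at the optimum (Wald).
#'
#' If the carrageenan-in-sheep flag does not vary in the data, its effects are
#' dropped (fixed at zero) with a warning.
#'
#' @param records A trial data frame (see [simulate_trial()] /
#'   [read_dataset()]); only plasma records are used.
#' @param dose_mg_per_kg Administered dose (mg/kg).
#' @param start Optional named vector of starting values on the internal
#'   (log/identity) scale; default is a crude data-driven start.
#' @param se Compute Wald standard errors (numerical Hessian)? Disable for
#'   speed in replicate simulation studies.
#' @param control A [fit_control()].
#' @return Object of class `c("plasma_fit", "cagepk_fit")` with components
#'   `estimates`, `se`, `rse_percent`, `ci_low`, `ci_high`, `p_values`
#'   (covariate effects), `loglik`, `converged`, `n_subjects`, `n_obs`, and
#'   the empirical-Bayes modes `eta`.
#' @export
fit_plasma <- function(records, dose_mg_per_kg = 4, start = NULL, se = TRUE,
                       control = fit_control()) {
  st <- .plasma_struct(records, dose_mg_per_kg)
  if (st$G < 2) stop("need at least 2 subjects with plasma data", call. = FALSE)
  if (min(table(st$gobs)) < 4)
    stop("every subject needs at least 4 post-dose plasma samples", call. = FALSE)

  estimable_carr <- length(unique(st$series$carr)) > 1
  if (!estimable_carr)
    warning("carrageenan-in-sheep does not vary; dropping its k12/k21 effects",
            call. = FALSE)
  free <- .plasma_theta_names
  if (!estimable_carr) free <- setdiff(free, c("b12", "b21"))

  theta0 <- .plasma_start(st)
  if (!is.null(start)) theta0[names(start)] <- start

  env <- new.env()
  env$eta <- matrix(0, st$G, 2)
  full_theta <- function(th) {
    out <- theta0
    out[setdiff(names(out), free)] <- 0  # dropped covariate effects stay 0
    out[free] <- th
    out
  }
  obj <- function(th) {
    tf <- full_theta(th)
    if (any(!is.finite(tf))) return(1e10)
    omega <- pmax(exp(c(tf[["lomega_V"]], tf[["lomega_CL"]])), control$omega_min)
    res <- .laplace_nll(env$eta, omega, .plasma_cond_fn(st, tf),
                        control$inner_tol, control$inner_max_iter, control$fd_step)
    if (!is.finite(res$nll)) return(1e10)
    env$eta <- res$eta
    res$nll
  }
  lower <- stats::setNames(rep(-Inf, length(free)), free)
  lower[grep("^lomega", free)] <- log(control$omega_min)
  lower["lb"] <- log(1e-6)
  opt <- .outer_optim(theta0[free], obj, lower, control)
  theta_hat <- full_theta(opt$par)

  .finish_fit(theta_hat, free, opt, obj, env, st,
              scale = c(lV = "log", lCL = "log", lk12 = "log", lk21 = "log",
                        b12 = "identity", b21 = "identity", lomega_V = "log",
                        lomega_CL = "log", lb = "log"),
              natural_names = c(lV = "V", lCL = "CL", lk12 = "k12", lk21 = "k21",
                                b12 = "beta_k12_carr_sheep",
                                b21 = "beta_k21_carr_sheep",
                                lomega_V = "omega_V", lomega_CL = "omega_CL",
                                lb = "b_plasma"),
              se = se, cls = "plasma_fit", control = control)
}

# Shared assembly of the Table-3-shaped fit object.
.finish_fit <- function(theta_hat, free, opt, obj, env, st, scale,
                        natural_names, se, cls, control) {
  est <- ifelse(scale[names(theta_hat)] == "log", exp(theta_hat), theta_hat)
  names(est) <- natural_names[names(theta_hat)]
  se_nat <- ci_lo <- ci_hi <- rep(NA_real_, length(est))
  names(se_nat) <- names(ci_lo) <- names(ci_hi) <- names(est)
  pvals <- NULL
  vcov_theta <- NULL
  if (se) {
    H <- try(stats::optimHess(opt$par, obj), silent = TRUE)
    V <- if (!inherits(H, "try-error")) try(solve(H), silent = TRUE) else H
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) && all(diag(V) > 0)) {
      vcov_theta <- V
      se_th <- sqrt(diag(V))
      names(se_th) <- free
      z <- stats::qnorm(0.975)
      for (nm in free) {
        nat <- natural_names[[nm]]
        if (scale[[nm]] == "log") {
          se_nat[nat] <- est[nat] * se_th[nm]           # delta method
          ci_lo[nat] <- exp(theta_hat[[nm]] - z * se_th[nm])
          ci_hi[nat] <- exp(theta_hat[[nm]] + z * se_th[nm])
        } else {
          se_nat[nat] <- se_th[nm]
          ci_lo[nat] <- theta_hat[[nm]] - z * se_th[nm]
          ci_hi[nat] <- theta_hat[[nm]] + z * se_th[nm]
        }
      }
      beta_nms <- names(est)[startsWith(names(est), "beta_")]
      beta_free <- beta_nms[!is.na(se_nat[beta_nms])]
      pvals <- stats::setNames(
        2 * stats::pnorm(-abs(est[beta_free] / se_nat[beta_free])), beta_free)
    } else {
      warning("singular or indefinite Hessian; standard errors unavailable",
              call. = FALSE)
    }
  }
  eta <- env$eta
  rownames(eta) <- as.character(st$sheep %||% st$cage_labels)
  # nlminb sometimes reports "false convergence" on Laplace objectives whose
  # inner solve leaves sub-tolerance noise; accept the optimum if the outer
  # gradient is numerically flat there.
  converged <- opt$convergence == 0
  if (!converged) {
    h <- 1e-5
    gmax <- max(vapply(seq_along(opt$par), function(k) {
      e <- numeric(length(opt$par)); e[k] <- h
      abs(obj(opt$par + e) - obj(opt$par - e)) / (2 * h)
    }, numeric(1)))
    converged <- is.finite(gmax) && gmax < 0.5
  }
  structure(list(estimates = est, se = se_nat,
                 rse_percent = 100 * se_nat / abs(est),
                 ci_low = ci_lo, ci_high = ci_hi, p_values = pvals,
                 loglik = -opt$objective,
                 converged = converged,
                 message = opt$message,
                 n_subjects = st$G, n_obs = st$n_obs,
                 eta = eta, theta = theta_hat, free = free,
                 vcov_theta = vcov_theta, scale = scale,
                 natural_names = natural_names,
                 data = st$records, dose = st$dose, control = control),
            class = c(cls, "cagepk_fit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical-Bayes individual plasma parameters
#'
#' Posterior modes of the per-sheep random effects given the fixed population
#' estimates of a converged [fit_plasma()] run, returned as individual V and
#' CL together with the population k12/k21 and their carrageenan effects
#' (needed to build each sheep-period plasma forcing function).
#'
#' @param fit A [fit_plasma()] result.
#' @param records Optional plasma records to compute modes for (possibly a
#'   single sheep); defaults to the fit's own data, whose modes are already
#'   available.
#' @return Data frame of class `"individual_estimates"` with one row per
#'   sheep: `sheep_id`, `eta_V`, `eta_CL`, `V`, `CL`; population fixed
#'   effects are attached as attribute `"pop"`.
#' @export
empirical_bayes <- function(fit, records = NULL) {
  stopifnot(inherits(fit, "plasma_fit"))
  if (!fit$converged)
    warning("plasma fit did not formally converge; using final parameter values",
            call. = FALSE)
  th <- fit$theta
  if (is.null(records)) {
    eta <- fit$eta
    sheep <- as.integer(rownames(eta))
  } else {
    st <- .plasma_struct(records, fit$dose)
    omega <- pmax(exp(c(th[["lomega_V"]], th[["lomega_CL"]])), fit$control$omega_min)
    res <- .laplace_nll(matrix(0, st$G, 2), omega, .plasma_cond_fn(st, th),
                        fit$control$inner_tol, fit$control$inner_max_iter,
                        fit$control$fd_step)
    if (!res$converged) stop("empirical-Bayes mode search failed for sheep ",
                             paste(st$sheep, collapse = ", "), call. = FALSE)
    eta <- res$eta
    sheep <- st$sheep
  }
  out <- data.frame(sheep_id = sheep, eta_V = eta[, 1], eta_CL = eta[, 2],
                    V = exp(th[["lV"]] + eta[, 1]),
                    CL = exp(th[["lCL"]] + eta[, 2]))
  attr(out, "pop") <- list(k12 = exp(th[["lk12"]]), k21 = exp(th[["lk21"]]),
                           beta_k12_carr_sheep = th[["b12"]],
                           beta_k21_carr_sheep = th[["b21"]],
                           dose = fit$dose)
  class(out) <- c("individual_estimates", "data.frame")
  out
}
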