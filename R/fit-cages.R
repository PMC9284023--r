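# Sequential NLME stage 2: cage kinetics conditional on individual plasma
# parameters (each sheep's fitted plasma curve is a fixed forcing function).

# Index structures for the cage data: groups are cages (sheep x side x
# length), series are cage x period (the plasma forcing and the
# carrageenan-in-cage flag change with period).
.cage_struct <- function(records, individuals) {
  cg <- records[records$matrix == "cage" & !records$below_dose_time &
                  records$time_h > 0, , drop = FALSE]
  if (nrow(cg) == 0) stop("no post-dose cage records", call. = FALSE)
  pop <- attr(individuals, "pop")
  miss <- setdiff(unique(cg$sheep_id), individuals$sheep_id)
  if (length(miss))
    stop("no individual plasma estimates for sheep ",
         paste(miss, collapse = ", "), call. = FALSE)

  ckey <- paste(cg$sheep_id, cg$side, cg$length_cm)
  cages <- unique(data.frame(key = ckey, sheep_id = cg$sheep_id, side = cg$side,
                             length_cm = cg$length_cm))
  ci <- match(ckey, cages$key)

  skey <- paste(ckey, cg$period)
  us <- !duplicated(skey)
  series <- data.frame(key = skey[us], cage = ci[us], sheep_id = cg$sheep_id[us],
                       period = cg$period[us], length_cm = cg$length_cm[us],
                       carr_cage = as.numeric(cg$carr_cage[us]),
                       carr_sheep = as.numeric(cg$carr_sheep[us]),
                       side_right = as.numeric(cg$side[us] == "right"))
  si <- match(skey, series$key)

  # plasma forcing macro-constants per series
  irow <- match(series$sheep_id, individuals$sheep_id)
  lf <- ls <- cf <- cs <- numeric(nrow(series))
  for (s in seq_len(nrow(series))) {
    p <- plasma_params(individuals$V[irow[s]], individuals$CL[irow[s]],
                       pop$k12 * exp(pop$beta_k12_carr_sheep * series$carr_sheep[s]),
                       pop$k21 * exp(pop$beta_k21_carr_sheep * series$carr_sheep[s]))
    m <- macro_constants(p, pop$dose)
    lf[s] <- m$lambda_fast; ls[s] <- m$lambda_slow
    cf[s] <- m$coef_fast;  cs[s] <- m$coef_slow
  }

  list(cages = cages, G = nrow(cages), series = series, si = si,
       gobs = ci, t = cg$time_h, y = cg$conc_ug_ml, n_obs = nrow(cg),
       lf_o = lf[si], ls_o = ls[si], cf_o = cf[si], cs_o = cs[si],
       forcing = list(lf = lf, ls = ls, cf = cf, cs = cs),
       dose = pop$dose, records = cg,
       cage_labels = with(cages, paste(sheep_id, side, length_cm, sep = ":")))
}

.cage_theta_names <- c("lk13", "lk31", "bl13", "bl31", "bc13", "bc31",
                       "bs13", "bs31", "lomega_k13", "lomega_k31", "lb")

# E(lam, k31, t) = (exp(-lam t) - exp(-k31 t))/(k31 - lam) and its first two
# derivatives in k31, with a Taylor branch through the k31 ~ lam degeneracy
# (x = (k31 - lam) t small).
.cage_e_derivs <- function(lam, k31, t) {
  d <- k31 - lam
  x <- d * t
  elam <- exp(-lam * t)
  E <- Ek <- Ekk <- numeric(length(x))
  ser <- abs(x) < 1e-3
  if (any(!ser)) {
    i <- !ser
    E[i] <- (elam * (-expm1(-x)) / d)[i]
    ek31 <- exp(-k31[i] * t[i])
    Ek[i] <- (t[i] * ek31 - E[i]) / d[i]
    Ekk[i] <- (-t[i]^2 * ek31 - 2 * Ek[i]) / d[i]
  }
  if (any(ser)) {
    i <- ser
    xi <- x[i]; ti <- t[i]; ei <- elam[i]
    E[i] <- ti * ei * (1 - xi / 2 + xi^2 / 6 - xi^3 / 24)
    Ek[i] <- ti^2 * ei * (-1 / 2 + xi / 3 - xi^2 / 8 + xi^3 / 30)
    Ekk[i] <- ti^3 * ei * (1 / 3 - xi / 4 + xi^2 / 10)
  }
  list(E = E, Ek = Ek, Ekk = Ekk)
}

# Analytic value/gradient/Hessian of the conditional data NLL per cage in the
# two inner coordinates (eta_k13, eta_k31). Uses df/deta1 = f (f is linear in
# k13 = exp(... + eta1)) and the chain rule through k31 = exp(... + eta2).
.cage_cond_deriv <- function(st, theta) {
  sr <- st$series
  lp13 <- theta[["lk13"]] + theta[["bl13"]] * sr$length_cm +
    theta[["bc13"]] * sr$carr_cage + theta[["bs13"]] * sr$side_right
  lp31 <- theta[["lk31"]] + theta[["bl31"]] * sr$length_cm +
    theta[["bc31"]] * sr$carr_cage + theta[["bs31"]] * sr$side_right
  b <- exp(theta[["lb"]])
  cage_of_series <- sr$cage
  si <- st$si
  gf <- st$gobs
  function(eta) {
    k13_o <- pmin(pmax(exp(lp13 + eta[cage_of_series, 1])[si], 1e-12), 1e8)
    k31_o <- pmin(pmax(exp(lp31 + eta[cage_of_series, 2])[si], 1e-12), 1e8)
    d1 <- .cage_e_derivs(st$lf_o, k31_o, st$t)
    d2 <- .cage_e_derivs(st$ls_o, k31_o, st$t)
    h <- st$cf_o * d1$E + st$cs_o * d2$E
    hp <- st$cf_o * d1$Ek + st$cs_o * d2$Ek
    hpp <- st$cf_o * d1$Ekk + st$cs_o * d2$Ekk
    f <- pmax(k13_o * h, 1e-12)
    fe2 <- k13_o * k31_o * hp
    fe22 <- k13_o * (k31_o * hp + k31_o^2 * hpp)
    r <- st$y - f
    l <- log(b) + log(f) + r^2 / (2 * b^2 * f^2) + 0.5 * log(2 * pi)
    lf1 <- 1 / f - r * st$y / (b^2 * f^3)
    lf2 <- -1 / f^2 + st$y * (f + 3 * r) / (b^2 * f^4)
    H <- array(0, c(st$G, 2, 2))
    H[, 1, 1] <- rowsum(lf2 * f^2 + lf1 * f, gf)
    H[, 1, 2] <- H[, 2, 1] <- rowsum((lf2 * f + lf1) * fe2, gf)
    H[, 2, 2] <- rowsum(lf2 * fe2^2 + lf1 * fe22, gf)
    list(g = as.vector(rowsum(l, gf)),
         grad = cbind(as.vector(rowsum(lf1 * f, gf)),
                      as.vector(rowsum(lf1 * fe2, gf))),
         H = H)
  }
}

.cage_cond_fn <- function(st, theta) {
  sr <- st$series
  lp13 <- theta[["lk13"]] + theta[["bl13"]] * sr$length_cm +
    theta[["bc13"]] * sr$carr_cage + theta[["bs13"]] * sr$side_right
  lp31 <- theta[["lk31"]] + theta[["bl31"]] * sr$length_cm +
    theta[["bc31"]] * sr$carr_cage + theta[["bs31"]] * sr$side_right
  b <- exp(theta[["lb"]])
  cage_of_series <- sr$cage
  si <- st$si
  function(eta) {
    k13_o <- pmin(pmax(exp(lp13 + eta[cage_of_series, 1])[si], 1e-12), 1e8)
    k31_o <- pmin(pmax(exp(lp31 + eta[cage_of_series, 2])[si], 1e-12), 1e8)
    f <- k13_o * (.cage_term(st$cf_o, st$lf_o, k31_o, st$t) +
                  .cage_term(st$cs_o, st$ls_o, k31_o, st$t))
    f <- pmax(f, 1e-300)
    nll <- log(b) + log(f) + (st$y - f)^2 / (2 * b^2 * f^2) + 0.5 * log(2 * pi)
    as.vector(rowsum(nll, st$gobs))
  }
}

# Naive two-stage starting values: per-series least squares on the log scale
# with k13 profiled out (the cage profile is linear in k13), k31 on a
# refined grid; then OLS of the log per-series estimates on the covariates.
.cage_start <- function(st) {
  ok <- st$y > 0
  n_series <- nrow(st$series)
  fs <- factor(st$si, levels = seq_len(n_series))
  best <- list(rss = rep(Inf, n_series), k31 = rep(0.1, n_series),
               lk13 = numeric(n_series))
  for (k31 in exp(seq(log(0.005), log(2), length.out = 40))) {
    h <- .cage_term(st$cf_o, st$lf_o, k31, st$t) +
         .cage_term(st$cs_o, st$ls_o, k31, st$t)
    r <- ifelse(ok & h > 0, log(st$y) - log(h), NA)
    m <- as.vector(tapply(r, fs, mean, na.rm = TRUE))
    rss <- as.vector(tapply((r - m[st$si])^2, fs, sum, na.rm = TRUE))
    upd <- which(is.finite(rss) & rss < best$rss)
    best$rss[upd] <- rss[upd]; best$k31[upd] <- k31; best$lk13[upd] <- m[upd]
  }
  sr <- st$series
  X <- cbind(1, sr$length_cm, sr$carr_cage, sr$side_right)
  fit13 <- stats::lm.fit(X, best$lk13)
  fit31 <- stats::lm.fit(X, log(best$k31))
  om13 <- stats::sd(tapply(fit13$residuals, sr$cage, mean))
  om31 <- stats::sd(tapply(fit31$residuals, sr$cage, mean))
  cl <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  c(lk13 = unname(fit13$coefficients[1]), lk31 = unname(fit31$coefficients[1]),
    bl13 = cl(unname(fit13$coefficients[2]), -1, 1),
    bl31 = cl(unname(fit31$coefficients[2]), -1, 1),
    bc13 = cl(unname(fit13$coefficients[3]) %||na% 0, -2, 2),
    bc31 = cl(unname(fit31$coefficients[3]) %||na% 0, -2, 2),
    bs13 = cl(unname(fit13$coefficients[4]) %||na% 0, -2, 2),
    bs31 = cl(unname(fit31$coefficients[4]) %||na% 0, -2, 2),
    lomega_k13 = log(cl(om13, 0.05, 2)), lomega_k31 = log(cl(om31, 0.05, 2)),
    lb = log(0.4))
}

`%||na%` <- function(a, b) if (length(a) == 0 || is.na(a)) b else a

#' Fit the cage transfer model (NLME, Laplace)
#'
#' Second stage of the sequential fit: with each sheep's plasma curve fixed at
#' its empirical-Bayes individual parameters, maximises the Laplace marginal
#' likelihood of the cage records over the typical transfer rates k13 and k31,
#' their log-linear covariate effects (per cm cage length, carrageenan in the
#' cage, right side), per-cage lognormal random-effect SDs, and the cage-fluid
#' proportional error coefficient.
#'
#' Covariate effects whose covariate does not vary in the data are dropped
#' (fixed at zero) with a warning.
#'
#' @param records Trial data frame; only cage records are used.
#' @param individuals An `"individual_estimates"` object from
#'   [empirical_bayes()], or a converged [fit_plasma()] result (empirical
#'   Bayes is then run internally).
#' @inheritParams fit_plasma
#' @return Object of class `c("cage_fit", "cagepk_fit")`; see [fit_plasma()].
#' @export
fit_cages <- function(records, individuals, start = NULL, se = TRUE,
                      control = fit_control()) {
  if (inherits(individuals, "plasma_fit")) individuals <- empirical_bayes(individuals)
  stopifnot(inherits(individuals, "individual_estimates"))
  st <- .cage_struct(records, individuals)

  free <- .cage_theta_names
  drop_if <- function(cond, nms, what) {
    if (cond) {
      warning(what, " does not vary; dropping its effects", call. = FALSE)
      free <<- setdiff(free, nms)
    }
  }
  drop_if(length(unique(st$series$length_cm)) < 2, c("bl13", "bl31"), "cage length")
  drop_if(length(unique(st$series$carr_cage)) < 2, c("bc13", "bc31"),
          "carrageenan-in-cage")
  drop_if(length(unique(st$series$side_right)) < 2, c("bs13", "bs31"), "cage side")

  theta0 <- .cage_start(st)
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
    omega <- pmax(exp(c(tf[["lomega_k13"]], tf[["lomega_k31"]])), control$omega_min)
    res <- .laplace_nll(env$eta, omega, .cage_cond_fn(st, tf),
                        control$inner_tol, control$inner_max_iter, control$fd_step,
                        deriv_fn = .cage_cond_deriv(st, tf))
    if (!is.finite(res$nll)) return(1e10)
    env$eta <- res$eta
    res$nll
  }
  lower <- stats::setNames(rep(-Inf, length(free)), free)
  lower[grep("^lomega", free)] <- log(control$omega_min)
  lower["lb"] <- log(1e-6)
  opt <- .outer_optim(theta0[free], obj, lower, control)
  theta_hat <- full_theta(opt$par)

  st$sheep <- NULL
  fit <- .finish_fit(theta_hat, free, opt, obj, env, st,
              scale = c(lk13 = "log", lk31 = "log", bl13 = "identity",
                        bl31 = "identity", bc13 = "identity", bc31 = "identity",
                        bs13 = "identity", bs31 = "identity",
                        lomega_k13 = "log", lomega_k31 = "log", lb = "log"),
              natural_names = c(lk13 = "k13", lk31 = "k31",
                                bl13 = "beta_k13_len", bl31 = "beta_k31_len",
                                bc13 = "beta_k13_carr_cage",
                                bc31 = "beta_k31_carr_cage",
                                bs13 = "beta_k13_side_right",
                                bs31 = "beta_k31_side_right",
                                lomega_k13 = "omega_k13",
                                lomega_k31 = "omega_k31", lb = "b_cage"),
              se = se, cls = "cage_fit", control = control)
  fit$cages <- st$cages
  fit$series <- st$series
  fit$forcing <- st$forcing
  fit
}

#' Individual cage rate constants from a cage fit
#'
#' Per cage-period transfer rates at the empirical-Bayes modes (typical value
#' adjusted for that cage's covariates times exp(eta)), with the corresponding
#' half-lives — the individual-estimate summaries by cage size are computed
#' from these.
#'
#' @param fit A [fit_cages()] result.
#' @return Data frame with columns `sheep_id`, `side`, `length_cm`, `period`,
#'   `carr_cage`, `k13`, `k31`, `t_half_k13`, `t_half_k31`.
#' @export
individual_cage_params <- function(fit) {
  stopifnot(inherits(fit, "cage_fit"))
  th <- fit$theta
  sr <- fit$series
  k13 <- exp(th[["lk13"]] + th[["bl13"]] * sr$length_cm +
             th[["bc13"]] * sr$carr_cage + th[["bs13"]] * sr$side_right +
             fit$eta[sr$cage, 1])
  k31 <- exp(th[["lk31"]] + th[["bl31"]] * sr$length_cm +
             th[["bc31"]] * sr$carr_cage + th[["bs31"]] * sr$side_right +
             fit$eta[sr$cage, 2])
  data.frame(sheep_id = sr$sheep_id, side = ifelse(sr$side_right == 1, "right", "left"),
             length_cm = sr$length_cm, period = sr$period,
             carr_cage = sr$carr_cage == 1,
             k13 = k13, k31 = k31,
             t_half_k13 = half_life_from_rate(k13),
             t_half_k31 = half_life_from_rate(k31))
}

#' Merged population parameter table
#'
#' Combines the plasma and cage fit results into one report table (estimate,
#' RSE%, 95% CI, p-value per row) with reference covariate levels shown as
#' fixed zeros.
#'
#' @param plasma_fit A [fit_plasma()] result.
#' @param cage_fit A [fit_cages()] result.
#' @return Data frame of class `"parameter_table"` with columns `parameter`,
#'   `units`, `estimate`, `rse_percent`, `ci_low`, `ci_high`, `p_value`,
#'   `reference`.
#' @export
parameter_table <- function(plasma_fit, cage_fit) {
  stopifnot(inherits(plasma_fit, "plasma_fit"), inherits(cage_fit, "cage_fit"))
  if (!plasma_fit$converged || !cage_fit$converged)
    stop("both fits must have converged", call. = FALSE)
  units <- c(V = "L/kg", CL = "L/h.kg", b_plasma = "", b_cage = "",
             omega_V = "L/kg", omega_CL = "L/h.kg")
  row <- function(fit, nat, ref = FALSE, label = nat) {
    if (ref)
      return(data.frame(parameter = label, units = "h^-1", estimate = 0,
                        rse_percent = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_value = NA_real_, reference = TRUE))
    data.frame(parameter = label,
               units = if (nat %in% names(units)) units[[nat]] else "h^-1",
               estimate = unname(fit$estimates[nat]),
               rse_percent = unname(fit$rse_percent[nat]),
               ci_low = unname(fit$ci_low[nat]), ci_high = unname(fit$ci_high[nat]),
               p_value = if (!is.null(fit$p_values) && nat %in% names(fit$p_values))
                 unname(fit$p_values[nat]) else NA_real_,
               reference = FALSE)
  }
  has <- function(fit, nat) nat %in% names(fit$estimates) &&
    is.finite(fit$estimates[nat])
  rows <- list(row(plasma_fit, "V"), row(plasma_fit, "k12"))
  if (has(plasma_fit, "beta_k12_carr_sheep")) {
    rows <- c(rows, list(row(NULL, "", ref = TRUE,
                             label = "beta_k12_carr_sheep (reference: none)"),
                         row(plasma_fit, "beta_k12_carr_sheep")))
  }
  rows <- c(rows, list(row(plasma_fit, "k21")))
  if (has(plasma_fit, "beta_k21_carr_sheep")) {
    rows <- c(rows, list(row(NULL, "", ref = TRUE,
                             label = "beta_k21_carr_sheep (reference: none)"),
                         row(plasma_fit, "beta_k21_carr_sheep")))
  }
  rows <- c(rows, list(row(plasma_fit, "CL"), row(cage_fit, "k31")))
  for (nm in c("beta_k31_side_right", "beta_k31_len", "beta_k31_carr_cage"))
    if (has(cage_fit, nm)) {
      if (grepl("side|carr", nm))
        rows <- c(rows, list(row(NULL, "", ref = TRUE,
                                 label = paste0(nm, " (reference level)"))))
      rows <- c(rows, list(row(cage_fit, nm)))
    }
  rows <- c(rows, list(row(cage_fit, "k13")))
  for (nm in c("beta_k13_side_right", "beta_k13_len", "beta_k13_carr_cage"))
    if (has(cage_fit, nm)) {
      if (grepl("side|carr", nm))
        rows <- c(rows, list(row(NULL, "", ref = TRUE,
                                 label = paste0(nm, " (reference level)"))))
      rows <- c(rows, list(row(cage_fit, nm)))
    }
  rows <- c(rows, list(row(plasma_fit, "omega_V"), row(plasma_fit, "omega_CL"),
                       row(cage_fit, "omega_k31"), row(cage_fit, "omega_k13"),
                       row(plasma_fit, "b_plasma"), row(cage_fit, "b_cage")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("parameter_table", "data.frame")
  attr(out, "footnote") <-
    "Reference levels (left side, no carrageenan) are fixed at zero."
  out
}

#' @export
print.parameter_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], signif, digits = digits)
  print(y, row.names = FALSE)
  cat("*", attr(x, "footnote"), "\n")
  invisible(x)
}
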