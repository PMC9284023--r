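# S3 methods for the NLME fit objects.

#' @export
print.cagepk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s: Laplace NLME fit, %d subjects/groups, %d observations\n",
              if (inherits(x, "plasma_fit")) "Plasma model" else "Cage model",
              x$n_subjects, x$n_obs))
  cat(sprintf("  log-likelihood %.2f, %s\n", x$loglik,
              if (x$converged) "converged" else paste("NOT converged:", x$message)))
  print(signif(x$estimates, digits))
  invisible(x)
}

#' @export
summary.cagepk_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates,
                    se = object$se,
                    rse_percent = object$rse_percent,
                    ci_low = object$ci_low,
                    ci_high = object$ci_high,
                    p_value = NA_real_)
  if (!is.null(object$p_values))
    tab[names(object$p_values), "p_value"] <- object$p_values
  structure(list(table = tab, loglik = object$loglik,
                 converged = object$converged,
                 n_subjects = object$n_subjects, n_obs = object$n_obs),
            class = "summary.cagepk_fit")
}

#' @export
print.summary.cagepk_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Laplace NLME fit: %d subjects/groups, %d observations, logLik %.2f (%s)\n",
              x$n_subjects, x$n_obs, x$loglik,
              if (x$converged) "converged" else "not converged"))
  tab <- x$table
  tab[] <- lapply(tab, signif, digits = digits)
  print(tab)
  invisible(x)
}

#' @export
coef.cagepk_fit <- function(object, ...) object$estimates

#' @export
logLik.cagepk_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$free), nobs = object$n_obs,
            class = "logLik")
}

#' @export
confint.cagepk_fit <- function(object, parm, level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% Wald interval computed at fit time is stored", call. = FALSE)
  ci <- cbind(`2.5 %` = object$ci_low, `97.5 %` = object$ci_high)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Individual-weighted residuals of an NLME fit
#'
#' (y - f) / (b f) with f the conditional prediction at the empirical-Bayes
#' modes; approximately standard normal when the model holds.
#'
#' @param object A [fit_plasma()] or [fit_cages()] result.
#' @param ... Unused.
#' @return Numeric vector, one residual per fitted observation.
#' @export
residuals.cagepk_fit <- function(object, ...) {
  f <- fitted(object)
  y <- object$data$conc_ug_ml
  b <- object$estimates[[if (inherits(object, "plasma_fit")) "b_plasma" else "b_cage"]]
  (y - f) / (b * f)
}

#' @export
fitted.plasma_fit <- function(object, ...) {
  th <- object$theta
  st <- .plasma_struct(object$data, object$dose)
  eta <- object$eta
  shp <- st$series$sheep
  V_s <- exp(th[["lV"]] + eta[shp, 1])
  CL_s <- exp(th[["lCL"]] + eta[shp, 2])
  k12_s <- exp(th[["lk12"]] + th[["b12"]] * st$series$carr)
  k21_s <- exp(th[["lk21"]] + th[["b21"]] * st$series$carr)
  k10 <- CL_s / V_s
  ssum <- k10 + k12_s + k21_s
  sq <- sqrt(ssum^2 - 4 * k10 * k21_s)
  lf <- (ssum + sq) / 2; ls <- (ssum - sq) / 2
  c0 <- st$dose / V_s
  cf <- c0 * (lf - k21_s) / sq
  cs <- c0 * (k21_s - ls) / sq
  cf[st$si] * exp(-lf[st$si] * st$t) + cs[st$si] * exp(-ls[st$si] * st$t)
}

#' @export
fitted.cage_fit <- function(object, ...) {
  th <- object$theta
  sr <- object$series
  ind <- individual_cage_params(object)
  d <- object$data
  si <- match(paste(d$sheep_id, d$side, d$length_cm, d$period),
              with(sr, paste(sheep_id, ifelse(side_right == 1, "right", "left"),
                             length_cm, period)))
  fo <- object$forcing
  ind$k13[si] * (.cage_term(fo$cf[si], fo$lf[si], ind$k31[si], d$time_h) +
                 .cage_term(fo$cs[si], fo$ls[si], ind$k31[si], d$time_h))
}

#' @export
plot.cagepk_fit <- function(x, ...) {
  f <- fitted(x)
  y <- x$data$conc_ug_ml
  graphics::plot(f, y, xlab = "Conditional prediction (ug/mL)",
                 ylab = "Observed (ug/mL)", ...)
  graphics::abline(0, 1, col = 2)
  invisible(x)
}
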