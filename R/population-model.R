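#' Log-linear covariate effects on the PK rate constants
#'
#' All covariates act multiplicatively on the log scale:
#' log k = log k_pop + sum(beta * covariate). Cage length enters uncentered in
#' cm; flags (carrageenan in the sheep, carrageenan in the cage, right side)
#' enter as 0/1 with left side / no carrageenan as the reference level
#' contributing zero.
#'
#' @param beta_k12_carr_sheep,beta_k21_carr_sheep Shift of k12/k21 when the
#'   animal carries carrageenan-inflamed cages (systemic inflammation).
#' @param beta_k13_len,beta_k31_len Shift of k13/k31 per cm of cage length.
#' @param beta_k13_carr_cage,beta_k31_carr_cage Shift when the cage itself is
#'   carrageenan-inflamed.
#' @param beta_k13_side_right,beta_k31_side_right Shift for right-side cages.
#' @return Object of class `"covariate_effects"`.
#' @export
covariate_effects <- function(beta_k12_carr_sheep = 0, beta_k21_carr_sheep = 0,
                              beta_k13_len = 0, beta_k31_len = 0,
                              beta_k13_carr_cage = 0, beta_k31_carr_cage = 0,
                              beta_k13_side_right = 0, beta_k31_side_right = 0) {
  vals <- list(beta_k12_carr_sheep = beta_k12_carr_sheep,
               beta_k21_carr_sheep = beta_k21_carr_sheep,
               beta_k13_len = beta_k13_len, beta_k31_len = beta_k31_len,
               beta_k13_carr_cage = beta_k13_carr_cage,
               beta_k31_carr_cage = beta_k31_carr_cage,
               beta_k13_side_right = beta_k13_side_right,
               beta_k31_side_right = beta_k31_side_right)
  if (any(!vapply(vals, function(x) is.finite(x) && length(x) == 1L, logical(1))))
    stop("covariate effects must be finite scalars", call. = FALSE)
  structure(vals, class = "covariate_effects")
}

#' Standard deviations of the lognormal random effects
#'
#' V and CL carry per-sheep effects (shared eta for a sheep across periods);
#' k13 and k31 carry independent per-cage effects. k12 and k21 carry none.
#'
#' @param omega_V,omega_CL,omega_k13,omega_k31 Log-scale SDs, >= 0.
#' @return Object of class `"random_effect_sds"`.
#' @export
random_effect_sds <- function(omega_V = 0, omega_CL = 0, omega_k13 = 0, omega_k31 = 0) {
  vals <- c(omega_V = omega_V, omega_CL = omega_CL,
            omega_k13 = omega_k13, omega_k31 = omega_k31)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("random-effect SDs must be finite and non-negative", call. = FALSE)
  structure(as.list(vals), class = "random_effect_sds")
}

#' Proportional residual-error coefficients
#'
#' Observations follow y = f * (1 + b * eps) with eps standard normal, so `b`
#' is the residual coefficient of variation; one coefficient for plasma and
#' one for cage fluid.
#'
#' @param b_plasma,b_cage Proportional error coefficients, >= 0.
#' @return Object of class `"error_model"`.
#' @export
error_model <- function(b_plasma = 0, b_cage = 0) {
  vals <- c(b_plasma = b_plasma, b_cage = b_cage)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("error coefficients must be finite and non-negative", call. = FALSE)
  structure(as.list(vals), class = "error_model")
}

#' Population pharmacokinetic model
#'
#' Bundles the typical-value plasma and cage parameters (at the reference
#' covariate level: left side, no carrageenan, and nominally 0 cm length for
#' the uncentered length covariate), the log-linear covariate effects, the
#' random-effect SDs, the proportional error model, and the dose.
#'
#' @param plasma A [plasma_params()] of population typical values.
#' @param cage A [cage_params()] of typical values at reference covariates.
#' @param covariates A [covariate_effects()].
#' @param omegas A [random_effect_sds()].
#' @param error An [error_model()].
#' @param dose_mg_per_kg Intravenous bolus dose (mg/kg).
#' @return Object of class `"population_model"`.
#' @seealso [default_population_model()] for the carprofen-in-sheep values.
#' @export
population_model <- function(plasma, cage, covariates = covariate_effects(),
                             omegas = random_effect_sds(), error = error_model(),
                             dose_mg_per_kg = 4) {
  stopifnot(inherits(plasma, "plasma_params"), inherits(cage, "cage_params"),
            inherits(covariates, "covariate_effects"),
            inherits(omegas, "random_effect_sds"), inherits(error, "error_model"))
  if (!is.finite(dose_mg_per_kg) || dose_mg_per_kg <= 0)
    stop("dose must be strictly positive", call. = FALSE)
  structure(list(plasma = plasma, cage = cage, covariates = covariates,
                 omegas = omegas, error = error, dose_mg_per_kg = dose_mg_per_kg),
            class = "population_model")
}

#' Reference population model for IV carprofen in sheep
#'
#' Typical values, covariate effects, random-effect SDs and proportional error
#' coefficients for a 4 mg/kg IV carprofen bolus in adult sheep carrying
#' 3-18 cm tissue cages: V = 0.0924 L/kg, CL = 0.00235 L/h/kg, k12 = 0.121,
#' k21 = 0.200, k13 = 0.124, k31 = 0.455 h^-1, with log-linear length effects
#' of -0.0378 (k13) and -0.147 (k31) per cm, carrageenan-in-cage effects of
#' -0.184 (k13) and -0.104 (k31), right-side effects of -0.024 (k13) and
#' -0.0701 (k31), a carrageenan-in-sheep effect of 0.00114 (k12) and 0.336
#' (k21), random-effect SDs 0.188 (V), 0.448 (CL), 0.482 (k13), 0.522 (k31),
#' and proportional errors 0.136 (plasma) and 0.468 (cage fluid).
#'
#' @return A [population_model()].
#' @export
default_population_model <- function() {
  population_model(
    plasma = plasma_params(V = 0.0924, CL = 0.00235, k12 = 0.121, k21 = 0.200),
    cage = cage_params(k13 = 0.124, k31 = 0.455),
    covariates = covariate_effects(
      beta_k12_carr_sheep = 0.00114, beta_k21_carr_sheep = 0.336,
      beta_k13_len = -0.0378, beta_k31_len = -0.147,
      beta_k13_carr_cage = -0.184, beta_k31_carr_cage = -0.104,
      beta_k13_side_right = -0.024, beta_k31_side_right = -0.0701),
    omegas = random_effect_sds(omega_V = 0.188, omega_CL = 0.448,
                               omega_k13 = 0.482, omega_k31 = 0.522),
    error = error_model(b_plasma = 0.136, b_cage = 0.468),
    dose_mg_per_kg = 4)
}

#' @export
print.population_model <- function(x, ...) {
  cat("Population PK model (two-compartment plasma + forcing-function cage)\n")
  cat(sprintf("  dose %g mg/kg IV bolus\n", x$dose_mg_per_kg))
  cat(sprintf("  V %.4g L/kg, CL %.4g L/h/kg, k12 %.4g, k21 %.4g h^-1\n",
              x$plasma$V, x$plasma$CL, x$plasma$k12, x$plasma$k21))
  cat(sprintf("  k13 %.4g, k31 %.4g h^-1 (reference covariates)\n",
              x$cage$k13, x$cage$k31))
  b <- unlist(x$covariates)
  if (any(b != 0)) {
    cat("  covariate effects (log-linear):\n")
    for (nm in names(b)[b != 0]) cat(sprintf("    %s = %.4g\n", nm, b[[nm]]))
  }
  cat(sprintf("  omegas: V %.3g, CL %.3g, k13 %.3g, k31 %.3g\n",
              x$omegas$omega_V, x$omegas$omega_CL, x$omegas$omega_k13, x$omegas$omega_k31))
  cat(sprintf("  proportional error: plasma %.3g, cage %.3g\n",
              x$error$b_plasma, x$error$b_cage))
  invisible(x)
}

#' Covariate-adjusted typical parameters for one cage context
#'
#' Applies the log-linear covariate model to the population typical values for
#' a cage of given length, inflammation status and side, and for the animal's
#' systemic inflammation status.
#'
#' @param m A [population_model()].
#' @param length_cm Cage length (cm), uncentered.
#' @param carr_cage Logical: carrageenan injected into this cage.
#' @param carr_sheep Logical: the animal has carrageenan cages in this period.
#' @param side_right Logical: cage implanted on the right side.
#' @return List with elements `plasma` ([plasma_params()]) and `cage`
#'   ([cage_params()]).
#' @export
apply_covariates <- function(m, length_cm, carr_cage = FALSE, carr_sheep = FALSE,
                             side_right = FALSE) {
  stopifnot(inherits(m, "population_model"), length_cm >= 0)
  cv <- m$covariates
  k12 <- m$plasma$k12 * exp(cv$beta_k12_carr_sheep * as.numeric(carr_sheep))
  k21 <- m$plasma$k21 * exp(cv$beta_k21_carr_sheep * as.numeric(carr_sheep))
  k13 <- m$cage$k13 * exp(cv$beta_k13_len * length_cm +
                          cv$beta_k13_carr_cage * as.numeric(carr_cage) +
                          cv$beta_k13_side_right * as.numeric(side_right))
  k31 <- m$cage$k31 * exp(cv$beta_k31_len * length_cm +
                          cv$beta_k31_carr_cage * as.numeric(carr_cage) +
                          cv$beta_k31_side_right * as.numeric(side_right))
  list(plasma = plasma_params(m$plasma$V, m$plasma$CL, k12, k21),
       cage = cage_params(k13, k31))
}

#' Draw individual parameters from the population model
#'
#' Multiplies the covariate-adjusted typical values by exp(eta) with
#' eta ~ N(0, omega^2): a shared per-sheep pair (eta_V, eta_CL) and an
#' independent per-cage pair (eta_k13, eta_k31). k12 and k21 carry no random
#' effects.
#'
#' @inheritParams apply_covariates
#' @param seed Optional integer seed for reproducible draws.
#' @return As [apply_covariates()], with lognormal individual deviations.
#' @export
draw_individual <- function(m, length_cm, carr_cage = FALSE, carr_sheep = FALSE,
                            side_right = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  typ <- apply_covariates(m, length_cm, carr_cage, carr_sheep, side_right)
  om <- m$omegas
  eta <- stats::rnorm(4) * c(om$omega_V, om$omega_CL, om$omega_k13, om$omega_k31)
  list(plasma = plasma_params(typ$plasma$V * exp(eta[1]), typ$plasma$CL * exp(eta[2]),
                              typ$plasma$k12, typ$plasma$k21),
       cage = cage_params(typ$cage$k13 * exp(eta[3]), typ$cage$k31 * exp(eta[4])))
}

#' Predicted concentration-time profiles from a population model
#'
#' Typical-value (random effects at zero) plasma and cage profiles for a given
#' cage context.
#'
#' @param object A [population_model()].
#' @param times Times since dose (h).
#' @param matrix `"plasma"` or `"cage"`.
#' @inheritParams apply_covariates
#' @param ... Unused.
#' @return Numeric vector of concentrations (ug/mL).
#' @export
predict.population_model <- function(object, times = seq(0, 72, by = 0.5),
                                     matrix = c("plasma", "cage"), length_cm = 3,
                                     carr_cage = FALSE, carr_sheep = FALSE,
                                     side_right = FALSE, ...) {
  matrix <- match.arg(matrix)
  pars <- apply_covariates(object, length_cm, carr_cage, carr_sheep, side_right)
  if (matrix == "plasma") plasma_conc(pars$plasma, object$dose_mg_per_kg, times)
  else cage_conc(pars$plasma, pars$cage, object$dose_mg_per_kg, times)
}

#' @export
plot.population_model <- function(x, lengths_cm = c(3, 6, 10, 14, 18),
                                  times = seq(0, 72, by = 0.25), log = "", ...) {
  pl <- predict(x, times, "plasma")
  curves <- lapply(lengths_cm, function(L) predict(x, times, "cage", length_cm = L))
  ylim <- range(c(pl, unlist(curves)), if (log == "y") NULL else 0)
  graphics::plot(times, pl, type = "l", lwd = 2, xlab = "Time (h)",
                 ylab = "Concentration (ug/mL)", ylim = ylim, log = log, ...)
  for (i in seq_along(curves))
    graphics::lines(times, curves[[i]], col = i + 1)
  graphics::legend("topright", bty = "n", lwd = c(2, rep(1, length(lengths_cm))),
                   col = c(1, seq_along(lengths_cm) + 1),
                   legend = c("plasma", paste0(lengths_cm, " cm cage")))
  invisible(x)
}

#' Write / read a population model as YAML
#'
#' Serialises all fields of a [population_model()] to a YAML file mirroring
#' the parameter names, and reads it back.
#'
#' @param m A [population_model()].
#' @param path File path.
#' @return `read_model_yaml()` returns a [population_model()].
#' @export
write_model_yaml <- function(m, path) {
  stopifnot(inherits(m, "population_model"))
  lst <- list(plasma = unclass(m$plasma), cage = unclass(m$cage),
              covariates = unclass(m$covariates), omegas = unclass(m$omegas),
              error = unclass(m$error), dose_mg_per_kg = m$dose_mg_per_kg)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  population_model(
    plasma = do.call(plasma_params, lst$plasma),
    cage = do.call(cage_params, lst$cage),
    covariates = do.call(covariate_effects, lst$covariates),
    omegas = do.call(random_effect_sds, lst$omegas),
    error = do.call(error_model, lst$error),
    dose_mg_per_kg = lst$dose_mg_per_kg)
}
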