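#' Plasma disposition parameters (two-compartment, IV bolus)
#'
#' @param V Central volume of distribution (L/kg).
#' @param CL Clearance from the central compartment (L/h/kg).
#' @param k12,k21 First-order central-peripheral transfer rates (h^-1).
#' @return Object of class `"plasma_params"`.
#' @export
plasma_params <- function(V, CL, k12, k21) {
  vals <- c(V = V, CL = CL, k12 = k12, k21 = k21)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("plasma parameters must all be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "plasma_params")
}

#' Tissue-cage transfer parameters
#'
#' Rate constants for drug movement into (`k13`) and out of (`k31`) the cage
#' compartment, which is driven by the central (plasma) concentration as a
#' forcing function: drug mass entering the cage is negligible relative to the
#' body, so the cage does not feed back on plasma kinetics.
#'
#' @param k13,k31 First-order transfer rates (h^-1).
#' @return Object of class `"cage_params"`.
#' @export
cage_params <- function(k13, k31) {
  vals <- c(k13 = k13, k31 = k31)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("cage parameters must be strictly positive", call. = FALSE)
  structure(as.list(vals), class = "cage_params")
}

#' Macro-constants of the two-compartment IV-bolus model
#'
#' Reparameterises (V, CL, k12, k21) into disposition exponents and
#' coefficients: C1(t) = coef_fast * exp(-lambda_fast * t) +
#' coef_slow * exp(-lambda_slow * t). The exponents are the roots of
#' lambda^2 - (k10 + k12 + k21) lambda + k10 k21 = 0 with k10 = CL/V.
#'
#' @param p A [plasma_params()].
#' @param dose Dose (mg/kg); with V in L/kg, concentrations are in ug/mL.
#' @return List of class `"macro_constants"` with `lambda_fast`, `lambda_slow`,
#'   `coef_fast`, `coef_slow`.
#' @export
macro_constants <- function(p, dose) {
  stopifnot(inherits(p, "plasma_params"), dose > 0)
  k10 <- p$CL / p$V
  s <- k10 + p$k12 + p$k21
  disc <- s^2 - 4 * k10 * p$k21
  stopifnot(disc >= 0)  # always true for positive rates
  lf <- (s + sqrt(disc)) / 2
  ls <- (s - sqrt(disc)) / 2
  c0 <- dose / p$V
  # coefficients from partial fractions: A = C0 (lf - k21)/(lf - ls), B = C0 (k21 - ls)/(lf - ls)
  cf <- c0 * (lf - p$k21) / (lf - ls)
  cs <- c0 * (p$k21 - ls) / (lf - ls)
  structure(list(lambda_fast = lf, lambda_slow = ls,
                 coef_fast = cf, coef_slow = cs),
            class = "macro_constants")
}

#' Plasma concentration after an IV bolus
#'
#' Biexponential closed form of the two-compartment model; linear in dose.
#'
#' @inheritParams macro_constants
#' @param t Time(s) since dose (h), non-negative.
#' @return Concentration(s) in ug/mL.
#' @export
plasma_conc <- function(p, dose, t) {
  if (any(t < 0)) stop("t must be non-negative (pre-dose handled by caller)", call. = FALSE)
  m <- macro_constants(p, dose)
  m$coef_fast * exp(-m$lambda_fast * t) + m$coef_slow * exp(-m$lambda_slow * t)
}

# Stable evaluation of (exp(-lam*t) - exp(-k31*t)) / (k31 - lam):
# exp(-lam t) * (-expm1(-(k31-lam) t)) / (k31 - lam), with the t*exp(-lam t)
# limit at k31 == lam. Vectorised over everything.
.cage_term <- function(coef, lam, k31, t) {
  d <- k31 - lam
  degen <- abs(d) < 1e-12 * pmax(lam, k31)
  out <- numeric(length(t))
  if (any(!degen)) {
    i <- !degen
    out[i] <- (coef * exp(-lam * t) * (-expm1(-d * t)) / d)[i]
  }
  if (any(degen)) {
    i <- degen
    out[i] <- (coef * t * exp(-lam * t))[i]
  }
  out
}

#' Tissue-cage concentration under the forcing-function model
#'
#' Solves dC3/dt = k13 C1(t) - k31 C3, C3(0) = 0, with C1 the biexponential
#' plasma profile, in closed form. The numerically delicate case k31 close to
#' a disposition exponent is evaluated through `expm1` so the profile is
#' smooth through the degeneracy.
#'
#' @inheritParams macro_constants
#' @param cg A [cage_params()].
#' @param t Time(s) since dose (h), non-negative.
#' @return Concentration(s) in ug/mL.
#' @export
cage_conc <- function(p, cg, dose, t) {
  stopifnot(inherits(cg, "cage_params"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  m <- macro_constants(p, dose)
  cg$k13 * (.cage_term(m$coef_fast, m$lambda_fast, cg$k31, t) +
            .cage_term(m$coef_slow, m$lambda_slow, cg$k31, t))
}

#' Time of the cage concentration peak
#'
#' The cage profile rises from zero (influx exceeds efflux) and then decays,
#' so it has a unique interior maximum; it is found by bracketed root-finding
#' on the time derivative k13 C1(t) - k31 C3(t).
#'
#' @inheritParams cage_conc
#' @param upper Initial upper bracket in h (expanded as needed).
#' @return Peak time (h).
#' @export
cage_tmax <- function(p, cg, dose, upper = 200) {
  deriv <- function(t) cg$k13 * plasma_conc(p, dose, t) - cg$k31 * cage_conc(p, cg, dose, t)
  hi <- upper
  for (i in 1:40) {
    if (deriv(hi) < 0) break
    hi <- hi * 2
  }
  if (deriv(hi) >= 0)
    stop("could not bracket the cage concentration peak (derivative still positive at t = ",
         signif(hi, 3), " h)", call. = FALSE)
  stats::uniroot(deriv, c(0, hi), tol = 1e-10)$root
}

#' Half-life from a first-order rate constant
#'
#' @param k Rate constant(s) (h^-1), strictly positive.
#' @return Half-life ln(2)/k in h.
#' @export
half_life_from_rate <- function(k) {
  if (any(!is.finite(k)) || any(k <= 0))
    stop("rate constant must be strictly positive", call. = FALSE)
  log(2) / k
}

#' Terminal plasma half-life
#'
#' ln(2) divided by the slow disposition exponent of the two-compartment
#' model.
#'
#' @inheritParams macro_constants
#' @export
terminal_half_life <- function(p) {
  log(2) / macro_constants(p, dose = 1)$lambda_slow
}
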