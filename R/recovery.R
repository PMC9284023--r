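# Simulate-and-refit recovery studies: the stand-in for parameter validation
# when no real concentration data are available.

#' PK simulate-and-refit recovery study
#'
#' Repeatedly simulates trials from a generating population model and re-fits
#' them with the sequential Laplace NLME (plasma, then optionally empirical
#' Bayes and the cage stage), returning the per-replicate population
#' estimates. The replicate mean against the generating value, with the
#' replicate SD/sqrt(n) as simulation standard error, measures estimator
#' recovery at a given design size.
#'
#' @param n_reps Number of replicate trials.
#' @param n_sheep Sheep per trial (cages and sampling times follow
#'   `design`).
#' @param seed Root seed; replicate r uses `seed + 1009 * r`.
#' @param model Generating [population_model()].
#' @param design Template [trial_design()]; its `n_sheep` is overridden and
#'   the carrageenan side re-randomised per replicate.
#' @param cages Also run the cage stage (slower)?
#' @param se Compute Wald SEs in each fit?
#' @param control A [fit_control()].
#' @return Data frame with one row per replicate: plasma estimates (and cage
#'   estimates when `cages = TRUE`), RSEs and CI bounds for V and CL when
#'   `se = TRUE`, and convergence flags.
#' @export
recovery_study <- function(n_reps = 20, n_sheep = 50, seed = 1,
                           model = default_population_model(),
                           design = trial_design(), cages = TRUE,
                           se = FALSE,
                           control = fit_control(rel_tol = 1e-6, x_tol = 1e-4,
                                                 inner_tol = 1e-7)) {
  design$n_sheep <- n_sheep
  design$carrageenan_side_by_sheep <- NULL
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    tr <- simulate_trial(design, model, seed = seed + 1009L * r)
    pf <- tryCatch(suppressWarnings(
      fit_plasma(tr, design$dose_mg_per_kg, se = se, control = control)),
      error = function(e) NULL)
    row <- data.frame(rep = r, plasma_converged = FALSE)
    if (!is.null(pf)) {
      row$plasma_converged <- pf$converged
      for (nm in c("V", "CL", "k12", "k21", "omega_V", "omega_CL", "b_plasma"))
        row[[nm]] <- unname(pf$estimates[nm])
      if (se) {
        for (nm in c("V", "CL")) {
          row[[paste0("rse_", nm)]] <- unname(pf$rse_percent[nm])
          row[[paste0("ci_low_", nm)]] <- unname(pf$ci_low[nm])
          row[[paste0("ci_high_", nm)]] <- unname(pf$ci_high[nm])
        }
      }
      if (cages) {
        cf <- tryCatch(suppressWarnings(
          fit_cages(tr, empirical_bayes(pf), se = se, control = control)),
          error = function(e) NULL)
        row$cage_converged <- !is.null(cf) && cf$converged
        if (!is.null(cf)) {
          for (nm in c("k13", "k31", "beta_k13_len", "beta_k31_len",
                       "omega_k13", "omega_k31", "b_cage"))
            row[[nm]] <- unname(cf$estimates[nm])
        }
      }
    }
    rows[[r]] <- row
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    # pad rows from failed replicates so columns align
    all_nms <- unique(unlist(lapply(rows, names)))
    r[setdiff(all_nms, names(r))] <- NA
    r[all_nms]
  }))
  rownames(out) <- NULL
  out
}

#' PGEM simulate-and-refit recovery study
#'
#' Repeatedly simulates PGEM records from a generating [pgem_model()] and
#' re-fits the linear mixed model, returning per-replicate fixed effects and
#' Nakagawa R-squared values.
#'
#' @inheritParams recovery_study
#' @param pgem Generating [pgem_model()].
#' @return Data frame with one row per replicate: `beta0`, `beta_time`,
#'   `r2_marginal`, `r2_conditional`, `n_obs`.
#' @export
pgem_recovery_study <- function(n_reps = 20, seed = 1,
                                pgem = default_pgem_model(),
                                design = trial_design()) {
  design$carrageenan_side_by_sheep <- NULL
  rows <- lapply(seq_len(n_reps), function(r) {
    pg <- simulate_pgem(design, pgem, seed = seed + 2003L * r)
    fit <- suppressWarnings(fit_pgem_lme(pg))
    r2 <- nakagawa_r2(fit)
    data.frame(rep = r, beta0 = unname(fit$fixef["(Intercept)"]),
               beta_time = unname(fit$fixef["time_h"]),
               r2_marginal = r2$marginal, r2_conditional = r2$conditional,
               n_obs = fit$n_obs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
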