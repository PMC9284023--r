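# End-to-end pipeline: simulate -> fit plasma -> empirical Bayes -> fit cages
# -> peak summaries and contrasts -> PGEM model, with table outputs.

#' Pipeline configuration
#'
#' Bundles the trial design, generating population model, PGEM model, root
#' seed and output directory. All stage randomness is derived from the root
#' seed through fixed per-stage offsets, so a run is fully reproducible.
#'
#' @param design A [trial_design()].
#' @param model A [population_model()] used to generate the trial.
#' @param pgem A [pgem_model()] used to generate PGEM records.
#' @param seed Root integer seed.
#' @param outdir Output directory for the TSV tables, or `NULL` to skip
#'   writing.
#' @param se Compute standard errors in the NLME fits (slower).
#' @param control A [fit_control()].
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(design = make_default_design(seed = 20190401),
                       model = default_population_model(),
                       pgem = default_pgem_model(),
                       seed = 20190401, outdir = NULL, se = TRUE,
                       control = fit_control()) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "population_model"),
            inherits(pgem, "pgem_model"), is.numeric(seed), length(seed) == 1,
            seed == round(seed))
  structure(list(design = design, model = model, pgem = pgem,
                 seed = as.integer(seed), outdir = outdir, se = se,
                 control = control),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `design`, `model`, `pgem` (fixed effects and variance
#' components), `seed`, `outdir`; missing keys fall back to the defaults of
#' [run_config()].
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lst <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(lst$design)) args$design <- do.call(trial_design, lst$design)
  if (!is.null(lst$model))
    args$model <- population_model(
      plasma = do.call(plasma_params, lst$model$plasma),
      cage = do.call(cage_params, lst$model$cage),
      covariates = do.call(covariate_effects, lst$model$covariates %||% list()),
      omegas = do.call(random_effect_sds, lst$model$omegas %||% list()),
      error = do.call(error_model, lst$model$error %||% list()),
      dose_mg_per_kg = lst$model$dose_mg_per_kg %||% 4)
  if (!is.null(lst$pgem))
    args$pgem <- pgem_model(lst$pgem$beta0, lst$pgem$beta_time,
                            unlist(lst$pgem$beta_size),
                            unlist(lst$pgem$beta_interaction),
                            lst$pgem$sd_sheep, lst$pgem$sd_resid)
  if (!is.null(lst$seed)) args$seed <- lst$seed
  if (!is.null(lst$outdir)) args$outdir <- lst$outdir
  do.call(run_config, args)
}

.stage_seed <- function(root, stage) (root + 7919L * stage) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' Simulates a trial from the configured design and population model, runs
#' the sequential NLME fit (plasma, empirical Bayes, cages), extracts peak
#' summaries and pairwise estimated-marginal-mean contrasts, simulates and
#' fits the PGEM mixed model, and assembles report tables: cage geometry,
#' the merged population parameter table, individual rate-constant summaries
#' by size, peak summaries, Cmax/Tmax contrasts, the PGEM coefficient table,
#' and a recovery summary comparing generating and estimated values. Tables
#' are written as TSV when the config has an `outdir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the simulated data, the three fits and all
#'   report tables.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  geometry <- stage("geometry", cage_table(sort(unique(config$design$cage_lengths_cm))))
  trial <- stage("simulate",
                 simulate_trial(config$design, config$model,
                                seed = .stage_seed(config$seed, 1L)))
  plasma <- stage("fit_plasma",
                  fit_plasma(trial, config$design$dose_mg_per_kg,
                             se = config$se, control = config$control))
  indiv <- stage("empirical_bayes", empirical_bayes(plasma))
  cages <- stage("fit_cages",
                 fit_cages(trial, indiv, se = config$se, control = config$control))
  params <- stage("parameter_table", parameter_table(plasma, cages))
  icp <- stage("individual_params", individual_cage_params(cages))
  rate_summary <- stage("rate_summary", {
    agg <- function(v, g) do.call(rbind, lapply(split(v, g), function(x)
      data.frame(min = min(x), median = stats::median(x), max = max(x))))
    k13 <- cbind(parameter = "k13", length_cm = sort(unique(icp$length_cm)),
                 agg(icp$k13, icp$length_cm),
                 t_half = agg(icp$t_half_k13, icp$length_cm))
    k31 <- cbind(parameter = "k31", length_cm = sort(unique(icp$length_cm)),
                 agg(icp$k31, icp$length_cm),
                 t_half = agg(icp$t_half_k31, icp$length_cm))
    out <- rbind(k13, k31)
    rownames(out) <- NULL
    out
  })
  peaks <- stage("peaks", observed_peaks(trial))
  peak_summary <- stage("peak_summary", summarize_peaks(peaks))
  contrasts_cmax <- stage("contrasts_cmax", emm_contrasts(peaks, "cmax"))
  contrasts_tmax <- stage("contrasts_tmax", emm_contrasts(peaks, "tmax"))
  pgem_data <- stage("simulate_pgem",
                     simulate_pgem(config$design, config$pgem,
                                   seed = .stage_seed(config$seed, 2L)))
  pgem_fit <- stage("fit_pgem", fit_pgem_lme(pgem_data))
  recovery <- stage("recovery", {
    gen <- c(V = config$model$plasma$V, CL = config$model$plasma$CL,
             k12 = config$model$plasma$k12, k21 = config$model$plasma$k21,
             k13 = config$model$cage$k13, k31 = config$model$cage$k31,
             beta_k13_len = config$model$covariates$beta_k13_len,
             beta_k31_len = config$model$covariates$beta_k31_len)
    est <- c(plasma$estimates[c("V", "CL", "k12", "k21")],
             cages$estimates[c("k13", "k31", "beta_k13_len", "beta_k31_len")])
    data.frame(parameter = names(gen), generating = unname(gen),
               estimated = unname(est),
               rel_error = unname((est - gen) / gen))
  })
  out <- list(geometry = geometry, trial = trial, plasma_fit = plasma,
              individuals = indiv, cage_fit = cages, parameter_table = params,
              rate_summary = rate_summary, peaks = peaks,
              peak_summary = peak_summary, contrasts_cmax = contrasts_cmax,
              contrasts_tmax = contrasts_tmax, pgem_data = pgem_data,
              pgem_fit = pgem_fit, pgem_r2 = nakagawa_r2(pgem_fit),
              recovery = recovery)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, name)
      utils::write.table(as.data.frame(df),
                         file.path(config$outdir, paste0(name, ".tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    wt(geometry, "geometry")
    wt(params, "population_parameters")
    wt(rate_summary, "rate_constants_by_size")
    wt(peak_summary, "peak_summary")
    wt(contrasts_cmax, "contrasts_cmax")
    wt(contrasts_tmax, "contrasts_tmax")
    wt(pgem_fit$table, "pgem_coefficients")
    wt(recovery, "recovery_summary")
  }
  invisible(out)
}
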