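#' Simulate a cross-over tissue-cage trial
#'
#' Generates long-format concentration records under the population model:
#' per-sheep lognormal deviations on V and CL (shared across periods),
#' independent per-cage deviations on k13 and k31 (shared across periods),
#' log-linear covariate effects per record context, closed-form plasma and
#' cage concentrations, and proportional residual error
#' y = f (1 + b eps) with negatives truncated at zero. Pre-dose samples
#' (t < 0) carry concentration zero and the `below_dose_time` flag.
#'
#' @param design A [trial_design()].
#' @param model A [population_model()].
#' @param seed Optional integer seed; the whole trial is reproducible from it.
#' @return A data frame of class `"cage_trial"` with columns `sheep_id`,
#'   `period`, `matrix` ("plasma"/"cage"), `side` ("none"/"left"/"right"),
#'   `length_cm` (0 for plasma), `carr_cage`, `carr_sheep`, `time_h`,
#'   `conc_ug_ml`, `below_dose_time`. The number of noise-truncated negative
#'   concentrations is attached as attribute `"n_truncated"`.
#' @examples
#' tr <- simulate_trial(make_default_design(seed = 1), default_population_model(), seed = 1)
#' nrow(tr)  # 7 * 2 * (14 + 10 * 14) = 2156
#' @export
simulate_trial <- function(design = make_default_design(),
                           model = default_population_model(), seed = NULL) {
  stopifnot(inherits(design, "trial_design"), inherits(model, "population_model"))
  if (!is.null(seed)) set.seed(seed)
  sides <- design$carrageenan_side_by_sheep
  if (is.null(sides))
    sides <- sample(c("left", "right"), design$n_sheep, replace = TRUE)

  tms <- design$sampling_times_h
  om <- model$omegas
  b_pl <- model$error$b_plasma
  b_cg <- model$error$b_cage
  dose <- design$dose_mg_per_kg
  cv <- model$covariates
  n_sheep <- design$n_sheep

  # random effects: per sheep (V, CL) and per cage (k13, k31), both shared
  # across periods; drawn in a fixed order for reproducibility
  eta_sheep <- matrix(stats::rnorm(2 * n_sheep), ncol = 2) %*%
    diag(c(om$omega_V, om$omega_CL), 2)
  cages <- expand.grid(side = c("left", "right"),
                       length_cm = design$cage_lengths_cm,
                       sheep_id = seq_len(n_sheep), stringsAsFactors = FALSE)
  eta_cage <- matrix(stats::rnorm(2 * nrow(cages)), ncol = 2) %*%
    diag(c(om$omega_k13, om$omega_k31), 2)

  # plasma series (sheep x period): individual macro-constants
  pser <- expand.grid(sheep_id = seq_len(n_sheep),
                      period = seq_len(design$n_periods))
  pser$carr_sheep <- pser$period == design$carrageenan_period
  V_s <- model$plasma$V * exp(eta_sheep[pser$sheep_id, 1])
  CL_s <- model$plasma$CL * exp(eta_sheep[pser$sheep_id, 2])
  k12_s <- model$plasma$k12 * exp(cv$beta_k12_carr_sheep * pser$carr_sheep)
  k21_s <- model$plasma$k21 * exp(cv$beta_k21_carr_sheep * pser$carr_sheep)
  k10 <- CL_s / V_s
  ssum <- k10 + k12_s + k21_s
  sq <- sqrt(ssum^2 - 4 * k10 * k21_s)
  lf <- (ssum + sq) / 2; ls <- (ssum - sq) / 2
  c0 <- dose / V_s
  cf <- c0 * (lf - k21_s) / sq
  cs <- c0 * (k21_s - ls) / sq

  ntm <- length(tms)
  pobs_s <- rep(seq_len(nrow(pser)), each = ntm)
  pt <- rep(tms, nrow(pser))
  post <- pt >= 0
  fpl <- numeric(length(pt))
  fpl[post] <- (cf[pobs_s] * exp(-lf[pobs_s] * pt) +
                cs[pobs_s] * exp(-ls[pobs_s] * pt))[post]
  plasma_rec <- data.frame(sheep_id = pser$sheep_id[pobs_s],
                           period = pser$period[pobs_s], matrix = "plasma",
                           side = "none", length_cm = 0, carr_cage = FALSE,
                           carr_sheep = pser$carr_sheep[pobs_s],
                           time_h = pt, conc_ug_ml = fpl,
                           below_dose_time = !post)

  # cage series (cage x period): covariate-adjusted individual rates
  cser <- merge(cbind(cages, cage_row = seq_len(nrow(cages))),
                data.frame(period = seq_len(design$n_periods)))
  cser$carr_sheep <- cser$period == design$carrageenan_period
  cser$carr_cage <- cser$carr_sheep & cser$side == sides[cser$sheep_id]
  cser$pser_row <- match(paste(cser$sheep_id, cser$period),
                         paste(pser$sheep_id, pser$period))
  k13_s <- model$cage$k13 * exp(cv$beta_k13_len * cser$length_cm +
    cv$beta_k13_carr_cage * cser$carr_cage +
    cv$beta_k13_side_right * (cser$side == "right") +
    eta_cage[cser$cage_row, 1])
  k31_s <- model$cage$k31 * exp(cv$beta_k31_len * cser$length_cm +
    cv$beta_k31_carr_cage * cser$carr_cage +
    cv$beta_k31_side_right * (cser$side == "right") +
    eta_cage[cser$cage_row, 2])

  cobs_s <- rep(seq_len(nrow(cser)), each = ntm)
  ct <- rep(tms, nrow(cser))
  cpost <- ct >= 0
  pr <- cser$pser_row[cobs_s]
  fcg <- numeric(length(ct))
  i <- which(cpost)
  fcg[i] <- k13_s[cobs_s][i] *
    (.cage_term(cf[pr][i], lf[pr][i], k31_s[cobs_s][i], ct[i]) +
     .cage_term(cs[pr][i], ls[pr][i], k31_s[cobs_s][i], ct[i]))
  cage_rec <- data.frame(sheep_id = cser$sheep_id[cobs_s],
                         period = cser$period[cobs_s], matrix = "cage",
                         side = cser$side[cobs_s],
                         length_cm = cser$length_cm[cobs_s],
                         carr_cage = cser$carr_cage[cobs_s],
                         carr_sheep = cser$carr_sheep[cobs_s],
                         time_h = ct, conc_ug_ml = fcg,
                         below_dose_time = !cpost)

  out <- rbind(plasma_rec, cage_rec)
  out <- out[order(out$sheep_id, out$period, out$matrix == "cage", out$side,
                   out$length_cm, out$time_h), ]

  # proportional residual error on post-dose records, truncated at zero
  obs <- !out$below_dose_time
  b <- ifelse(out$matrix == "plasma", b_pl, b_cg)[obs]
  y <- out$conc_ug_ml[obs] * (1 + b * stats::rnorm(sum(obs)))
  n_trunc <- sum(y < 0)
  out$conc_ug_ml[obs] <- pmax(y, 0)

  if (design$missing_rate > 0) {
    drop <- out$matrix == "cage" & stats::runif(nrow(out)) < design$missing_rate
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_truncated") <- n_trunc
  attr(out, "carrageenan_side_by_sheep") <- sides
  class(out) <- c("cage_trial", "data.frame")
  out
}

#' @export
simulate.population_model <- function(object, nsim = 1, seed = NULL,
                                      design = make_default_design(), ...) {
  if (!is.null(seed)) set.seed(seed)
  reps <- lapply(seq_len(nsim), function(i) simulate_trial(design, object))
  if (nsim == 1) reps[[1]] else reps
}

#' Simulate prostaglandin-E-metabolite (PGEM) records
#'
#' Generates log10 PGEM concentrations from the linear predictor
#' beta0 + beta_time * t + beta_size(L) + beta_interaction(L) * t with a
#' per-sheep Normal random intercept and Normal residuals, for the
#' carrageenan-side cages of the carrageenan period plus a random subsample of
#' the non-inflamed-side cages (the study assayed inflamed cages
#' preferentially, roughly 205 inflamed vs 74 non-inflamed records).
#'
#' @param design A [trial_design()].
#' @param pgem A [pgem_model()].
#' @param seed Optional integer seed.
#' @param times_h PGEM sampling times (h since dose).
#' @param noncarr_fraction Inclusion probability for non-carrageenan-side cage
#'   records (default 74/210, reproducing the study's imbalance).
#' @return Data frame with columns `sheep_id`, `side`, `length_cm`,
#'   `carr_cage`, `time_h`, `pgem_pg_ml`.
#' @export
simulate_pgem <- function(design = make_default_design(),
                          pgem = default_pgem_model(), seed = NULL,
                          times_h = c(0.5, 6, 12, 24, 48, 72),
                          noncarr_fraction = 74 / 210) {
  stopifnot(inherits(design, "trial_design"), inherits(pgem, "pgem_model"))
  if (!is.null(seed)) set.seed(seed)
  sides <- design$carrageenan_side_by_sheep
  if (is.null(sides))
    sides <- sample(c("left", "right"), design$n_sheep, replace = TRUE)
  grid <- expand.grid(sheep_id = seq_len(design$n_sheep),
                      side = c("left", "right"),
                      length_cm = design$cage_lengths_cm,
                      time_h = times_h,
                      stringsAsFactors = FALSE)
  grid$carr_cage <- grid$side == sides[grid$sheep_id]
  keep <- grid$carr_cage | stats::runif(nrow(grid)) < noncarr_fraction
  grid <- grid[keep, , drop = FALSE]
  gamma <- stats::rnorm(design$n_sheep, 0, pgem$sd_sheep)
  lp <- predict_pgem_curve(pgem, grid$length_cm, grid$time_h)
  y <- lp + gamma[grid$sheep_id] + stats::rnorm(nrow(grid), 0, pgem$sd_resid)
  out <- data.frame(sheep_id = grid$sheep_id, side = grid$side,
                    length_cm = grid$length_cm, carr_cage = grid$carr_cage,
                    time_h = grid$time_h, pgem_pg_ml = 10^y)
  out <- out[order(out$sheep_id, out$side, out$length_cm, out$time_h), ]
  rownames(out) <- NULL
  out
}

.dataset_cols <- c("sheep_id", "period", "matrix", "side", "length_cm",
                   "carr_cage", "carr_sheep", "time_h", "conc_ug_ml",
                   "below_dose_time")

#' Write / read a trial dataset as CSV
#'
#' Long-format CSV with a fixed header (`sheep_id, period, matrix, side,
#' length_cm, carr_cage, carr_sheep, time_h, conc_ug_ml, below_dose_time`);
#' a write-then-read round trip preserves all fields.
#'
#' @param records A `"cage_trial"` data frame (see [simulate_trial()]).
#' @param path File path.
#' @return `read_dataset()` returns the validated `"cage_trial"` data frame.
#' @export
write_dataset <- function(records, path) {
  stopifnot(is.data.frame(records))
  miss <- setdiff(.dataset_cols, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  utils::write.csv(as.data.frame(records)[.dataset_cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.dataset_cols, names(df))
  if (length(miss))
    stop("malformed dataset ", path, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[.dataset_cols]
  for (col in c("time_h", "conc_ug_ml", "length_cm")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad))
      stop("malformed dataset ", path, ": non-numeric '", col, "' at data row ",
           bad[1], call. = FALSE)
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("carr_cage", "carr_sheep", "below_dose_time")) {
    v <- df[[col]]
    if (is.character(v)) v <- toupper(v) == "TRUE"
    if (!is.logical(v) || anyNA(v))
      stop("malformed dataset ", path, ": column '", col,
           "' must be TRUE/FALSE", call. = FALSE)
    df[[col]] <- v
  }
  bad <- which(!df$matrix %in% c("plasma", "cage"))
  if (length(bad))
    stop("malformed dataset ", path, ": column 'matrix' must be plasma/cage at data row ",
         bad[1], call. = FALSE)
  bad <- which(df$conc_ug_ml < 0)
  if (length(bad))
    stop("malformed dataset ", path, ": negative concentration at data row ",
         bad[1], call. = FALSE)
  class(df) <- c("cage_trial", "data.frame")
  df
}

#' Export a trial dataset in Monolix/NONMEM-style layout
#'
#' One dosing line per sheep-period (`AMT` set, `DV` missing) followed by
#' observation lines, with columns `ID, TIME, DV, AMT, YTYPE, PERIOD, SIDE,
#' LENGTH, CARRCAGE, CARRSHEEP`. `YTYPE` is 1 for plasma and 2 for cage fluid;
#' pre-dose records are omitted.
#'
#' @inheritParams write_dataset
#' @param dose_mg_per_kg Dose recorded on the dosing lines.
#' @export
write_monolix <- function(records, path, dose_mg_per_kg = 4) {
  obs <- records[!records$below_dose_time, , drop = FALSE]
  obs_lines <- data.frame(ID = obs$sheep_id, TIME = obs$time_h,
                          DV = obs$conc_ug_ml, AMT = NA_real_,
                          YTYPE = ifelse(obs$matrix == "plasma", 1L, 2L),
                          PERIOD = obs$period, SIDE = obs$side,
                          LENGTH = obs$length_cm,
                          CARRCAGE = as.integer(obs$carr_cage),
                          CARRSHEEP = as.integer(obs$carr_sheep))
  dosing <- unique(data.frame(ID = obs$sheep_id, PERIOD = obs$period))
  dose_lines <- data.frame(ID = dosing$ID, TIME = 0, DV = NA_real_,
                           AMT = dose_mg_per_kg, YTYPE = NA_integer_,
                           PERIOD = dosing$PERIOD, SIDE = "none", LENGTH = 0,
                           CARRCAGE = 0L, CARRSHEEP = NA_integer_)
  all_lines <- rbind(dose_lines, obs_lines)
  all_lines <- all_lines[order(all_lines$ID, all_lines$PERIOD, all_lines$TIME,
                               !is.na(all_lines$DV)), ]
  utils::write.csv(all_lines, path, row.names = FALSE, na = ".")
  invisible(path)
}
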