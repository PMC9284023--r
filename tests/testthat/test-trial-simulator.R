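test_that("the default cross-over design has the study dimensions", {
  d <- make_default_design(seed = 1)
  expect_equal(d$n_sheep, 7)
  expect_equal(length(d$cage_lengths_cm) * 2, 10)
  expect_equal(length(d$sampling_times_h), 14)
  expect_equal(d$n_periods, 2)
  expect_equal(d$dose_mg_per_kg, 4)
  expect_true(all(d$carrageenan_side_by_sheep %in% c("left", "right")))
  expect_identical(make_default_design(seed = 5)$carrageenan_side_by_sheep,
                   make_default_design(seed = 5)$carrageenan_side_by_sheep)
  expect_error(trial_design(sampling_times_h = c(1, 1, 2)), "increasing")
  expect_error(trial_design(carrageenan_period = 3, n_periods = 2), "period")
})

test_that("a complete simulated trial has the design's record structure", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  expect_equal(nrow(tr), 7 * 2 * (14 + 10 * 14))  # 2156
  cg <- tr[tr$matrix == "cage", ]
  expect_equal(as.integer(table(cg$length_cm)), rep(392L, 5))  # 28 series x 14 times
  # covariate combinations exactly span the design: no orphan flags
  expect_true(all(!tr$carr_cage[tr$period != d$carrageenan_period]))
  expect_true(all(tr$carr_sheep == (tr$period == d$carrageenan_period)))
  carr <- cg[cg$carr_cage, ]
  expect_equal(sort(unique(paste(carr$sheep_id, carr$side))),
               sort(paste(seq_len(7), d$carrageenan_side_by_sheep)))
  # pre-dose records are flagged and zero
  expect_true(all(tr$conc_ug_ml[tr$below_dose_time] == 0))
  expect_true(all(tr$time_h[tr$below_dose_time] < 0))
  expect_true(all(tr$side[tr$matrix == "plasma"] == "none"))
  expect_true(all(tr$length_cm[tr$matrix == "plasma"] == 0))
})

test_that("simulation is deterministic under seed and distinct across seeds", {
  d <- make_default_design(seed = 3)
  a <- simulate_trial(d, default_population_model(), seed = 10)
  b <- simulate_trial(d, default_population_model(), seed = 10)
  c <- simulate_trial(d, default_population_model(), seed = 11)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$conc_ug_ml, c$conc_ug_ml)))
})

test_that("the noise-free limit reproduces the closed forms exactly", {
  m0 <- default_population_model()
  m0$omegas <- random_effect_sds()
  m0$error <- error_model()
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, m0, seed = 2)
  expect_equal(attr(tr, "n_truncated"), 0L)
  sel <- tr$matrix == "cage" & !tr$below_dose_time & tr$length_cm == 10 &
    tr$side == "right" & tr$period == 1 & tr$sheep_id == 4
  s <- tr[sel, ]
  pars <- apply_covariates(m0, 10, carr_cage = FALSE, carr_sheep = FALSE,
                           side_right = TRUE)
  expect_equal(s$conc_ug_ml,
               cage_conc(pars$plasma, pars$cage, 4, s$time_h), tolerance = 1e-12)
  pl <- tr[tr$matrix == "plasma" & !tr$below_dose_time & tr$sheep_id == 1 &
             tr$period == 1, ]
  expect_equal(pl$conc_ug_ml, plasma_conc(m0$plasma, 4, pl$time_h),
               tolerance = 1e-12)
})

test_that("proportional error has the configured coefficient of variation", {
  m <- default_population_model()
  m$omegas <- random_effect_sds()  # isolate residual noise
  d <- trial_design(n_sheep = 150)
  d$carrageenan_side_by_sheep <- rep("left", 150)
  tr <- simulate_trial(d, m, seed = 9)
  pl <- tr[tr$matrix == "plasma" & tr$time_h == 1 & tr$period == 1, ]
  expect_equal(sd(pl$conc_ug_ml) / mean(pl$conc_ug_ml), 0.136, tolerance = 0.15)
})

test_that("missingness drops cage records at the configured rate", {
  d <- make_default_design(seed = 1)
  d$missing_rate <- 0.2
  tr <- simulate_trial(d, default_population_model(), seed = 4)
  n_cage <- sum(tr$matrix == "cage")
  expect_lt(abs(n_cage - 0.8 * 1960), 4 * sqrt(1960 * 0.2 * 0.8))
  expect_equal(sum(tr$matrix == "plasma"), 196)  # plasma never dropped
})

test_that("dataset CSV write/read round-trips and validates", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_dataset(tr, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(tr)[names(back)],
               tolerance = 1e-12)
  # header-only file for an empty record set
  write_dataset(tr[0, ], path)
  expect_equal(nrow(read_dataset(path)), 0)
})

test_that("a hand-written CSV parses to records with correct flags", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c(
    "sheep_id,period,matrix,side,length_cm,carr_cage,carr_sheep,time_h,conc_ug_ml,below_dose_time",
    "1,1,plasma,none,0,FALSE,FALSE,0.5,41.2,FALSE",
    "1,1,cage,left,3,TRUE,TRUE,8,12.5,FALSE",
    "2,2,cage,right,18,FALSE,TRUE,-1,0,TRUE"), path)
  rec <- read_dataset(path)
  expect_equal(nrow(rec), 3)
  expect_identical(rec$carr_cage, c(FALSE, TRUE, FALSE))
  expect_identical(rec$below_dose_time, c(FALSE, FALSE, TRUE))
  expect_equal(rec$conc_ug_ml, c(41.2, 12.5, 0))
})

test_that("malformed CSV files are rejected with located errors", {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  writeLines(c(
    "sheep_id,period,matrix,side,length_cm,carr_cage,carr_sheep,time_h,conc_ug_ml,below_dose_time",
    "1,1,serum,none,0,FALSE,FALSE,0.5,41.2,FALSE"), path)
  expect_error(read_dataset(path), "matrix.*row 1")
  writeLines(c(
    "sheep_id,period,matrix,side,length_cm,carr_cage,carr_sheep,time_h,conc_ug_ml,below_dose_time",
    "1,1,plasma,none,0,FALSE,FALSE,0.5,-3,FALSE"), path)
  expect_error(read_dataset(path), "negative concentration")
  writeLines("sheep_id,period", path)
  expect_error(read_dataset(path), "missing column")
})

test_that("Monolix-style export has dosing lines and covariate columns", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_monolix(tr, path)
  mx <- read.csv(path, na.strings = ".")
  expect_equal(sum(!is.na(mx$AMT)), 7 * 2)        # one dosing line per occasion
  expect_equal(sum(!is.na(mx$DV)), sum(!tr$below_dose_time))
  expect_setequal(mx$YTYPE[!is.na(mx$YTYPE)], c(1, 2))
})

test_that("simulated PGEM records reflect the study's sampling imbalance", {
  d <- make_default_design(seed = 1)
  pg <- simulate_pgem(d, default_pgem_model(), seed = 5)
  expect_true(all(pg$pgem_pg_ml > 0))
  expect_equal(sum(pg$carr_cage), 7 * 5 * 6)      # inflamed side fully sampled
  expect_lt(abs(sum(!pg$carr_cage) - 74), 4 * sqrt(74))
  # noise-free generator reproduces the linear predictor exactly
  pgm <- default_pgem_model()
  pgm$sd_sheep <- 0; pgm$sd_resid <- 1e-12
  pg0 <- simulate_pgem(d, pgm, seed = 5)
  expect_equal(log10(pg0$pgem_pg_ml),
               predict_pgem_curve(pgm, pg0$length_cm, pg0$time_h),
               tolerance = 1e-6)
})
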