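# Sequential NLME estimation: exact-data limits, empirical Bayes, invariances
# and the report table.

# In the vanishing-noise limit the generating values must be recovered almost
# exactly. Exact zero proportional error makes the likelihood singular (the
# error coefficient runs to its floor and the objective surface degenerates
# into a needle), so the limit is probed at a tiny positive error level where
# the sampling error of every estimate is far below the test tolerance.
noise_free_model <- function() {
  m <- default_population_model()
  m$omegas <- random_effect_sds()
  m$error <- error_model(b_plasma = 0.005, b_cage = 0.005)
  m
}

test_that("the exact-data limit recovers the generating plasma parameters", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, noise_free_model(), seed = 2)
  fit <- suppressWarnings(fit_plasma(tr, se = FALSE))
  est <- fit$estimates
  expect_equal(unname(est["V"]), 0.0924, tolerance = 1e-2)
  expect_equal(unname(est["CL"]), 0.00235, tolerance = 1e-2)
  expect_equal(unname(est["k12"]), 0.121, tolerance = 2e-2)
  expect_equal(unname(est["k21"]), 0.200, tolerance = 2e-2)
  expect_lt(unname(est["omega_V"]), 0.05)
  expect_lt(unname(est["b_plasma"]), 0.01)
})

test_that("the exact-data limit recovers the generating cage parameters", {
  d <- make_default_design(seed = 1)
  m0 <- noise_free_model()
  tr <- simulate_trial(d, m0, seed = 2)
  pf <- suppressWarnings(fit_plasma(tr, se = FALSE))
  cf <- suppressWarnings(fit_cages(tr, empirical_bayes(pf), se = FALSE))
  est <- cf$estimates
  expect_equal(unname(est["k13"]), 0.124, tolerance = 1e-2)
  expect_equal(unname(est["k31"]), 0.455, tolerance = 1e-2)
  expect_equal(unname(est["beta_k13_len"]), -0.0378, tolerance = 1e-2)
  expect_equal(unname(est["beta_k31_len"]), -0.147, tolerance = 1e-2)
  expect_equal(unname(est["beta_k13_carr_cage"]), -0.184, tolerance = 0.02)
  expect_equal(unname(est["beta_k31_carr_cage"]), -0.104, tolerance = 0.05)
})

test_that("empirical Bayes shrinks to population values as omega vanishes", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  fit <- fit_plasma(tr, se = FALSE)
  # force tiny omegas in the fitted object and recompute modes
  fit$theta[["lomega_V"]] <- log(1e-6)
  fit$theta[["lomega_CL"]] <- log(1e-6)
  ind <- empirical_bayes(fit, tr)
  expect_equal(ind$V, rep(unname(fit$estimates["V"]), 7), tolerance = 1e-4)
  expect_equal(ind$CL, rep(unname(fit$estimates["CL"]), 7), tolerance = 1e-4)
})

test_that("empirical Bayes recovers simulated individuals from rich data", {
  # one sheep with noise-free data and a known random effect
  m <- default_population_model()
  d <- trial_design(n_sheep = 2)
  d$carrageenan_side_by_sheep <- c("left", "right")
  m0 <- m; m0$error <- error_model(b_plasma = 0.002, b_cage = 0.002)
  set.seed(11)
  tr <- simulate_trial(d, m0)
  fit <- suppressWarnings(fit_plasma(tr, se = FALSE))
  ind <- empirical_bayes(fit)
  # conditional predictions at the modes reproduce the noise-free data
  y <- fit$data$conc_ug_ml
  expect_lt(max(abs(fitted(fit) - y) / y), 0.02)
  # and the implied individual parameters differ between the two sheep
  expect_gt(abs(diff(log(ind$V))) + abs(diff(log(ind$CL))), 0.01)
})

test_that("cage estimates are invariant to record order", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  pf <- fit_plasma(tr, se = FALSE)
  ind <- empirical_bayes(pf)
  cf1 <- fit_cages(tr, ind, se = FALSE)
  set.seed(99)
  trs <- tr[sample(nrow(tr)), ]
  cf2 <- fit_cages(trs, ind, se = FALSE)
  # summation order perturbs the objective at machine precision, so the two
  # optima agree to optimizer tolerance rather than exactly
  expect_equal(cf1$estimates, cf2$estimates, tolerance = 1e-2)
})

test_that("non-identifiable covariate effects are dropped with a warning", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  # remove the non-carrageenan period: carrageenan-in-sheep no longer varies
  tr1 <- tr[tr$period == d$carrageenan_period, ]
  expect_warning(f1 <- fit_plasma(tr1, se = FALSE), "carrageenan-in-sheep")
  expect_false("beta_k21_carr_sheep" %in% f1$free)
  # single cage length: length effect not estimable
  pf <- fit_plasma(tr, se = FALSE)
  ind <- empirical_bayes(pf)
  tr3 <- tr[tr$matrix == "cage" & tr$length_cm == 3, ]
  expect_warning(c3 <- fit_cages(tr3, ind, se = FALSE), "cage length")
  expect_false("beta_k13_len" %in% names(c3$estimates) &&
                 is.finite(c3$se[["beta_k13_len"]]))
})

test_that("estimates agree with an independent NLME implementation", {
  # one-compartment plasma-like problem fit by both engines
  set.seed(21)
  n <- 12; times <- c(0.5, 1, 2, 4, 8, 16, 24, 48)
  V <- 0.1; CL <- 0.004; omega <- 0.3; b <- 0.1
  dat <- do.call(rbind, lapply(seq_len(n), function(i) {
    Vi <- V * exp(rnorm(1, 0, omega))
    f <- 4 / Vi * exp(-CL / Vi * times)
    data.frame(id = i, t = times, y = f * (1 + b * rnorm(length(times))))
  }))
  nl <- nlme::nlme(y ~ 4 / exp(lV) * exp(-exp(lCL) / exp(lV) * t),
                   fixed = lV + lCL ~ 1, random = lV ~ 1 | id,
                   data = dat, start = c(lV = log(0.12), lCL = log(0.003)),
                   weights = nlme::varPower(fixed = 1),
                   method = "ML")
  # same model through the package machinery (two-compartment collapse is not
  # used here; instead fit the cage-free plasma model with k12/k21 pinned by
  # a custom conditional likelihood through the Laplace core)
  ids <- unique(dat$id)
  cond <- function(th) function(eta) {
    vapply(seq_along(ids), function(i) {
      s <- dat[dat$id == ids[i], ]
      Vi <- exp(th[1] + eta[i, 1])
      f <- 4 / Vi * exp(-exp(th[2]) / Vi * s$t)
      sum(log(exp(th[3]) * f) + (s$y - f)^2 / (2 * exp(2 * th[3]) * f^2) +
            0.5 * log(2 * pi))
    }, numeric(1))
  }
  env <- new.env(); env$eta <- matrix(0, n, 1)
  obj <- function(th) {
    r <- cagepk:::.laplace_nll(env$eta, exp(th[4]), cond(th),
                               inner_tol = 1e-9, inner_max_iter = 100)
    env$eta <- r$eta
    r$nll
  }
  opt <- nlminb(c(log(0.12), log(0.003), log(0.2), log(0.2)), obj)
  expect_equal(exp(opt$par[1]), exp(nlme::fixef(nl)[["lV"]]), tolerance = 0.02)
  expect_equal(exp(opt$par[2]), exp(nlme::fixef(nl)[["lCL"]]), tolerance = 0.02)
  expect_equal(exp(opt$par[4]),
               as.numeric(nlme::VarCorr(nl)["lV", "StdDev"]), tolerance = 0.1)
})

test_that("the merged parameter table is Table-shaped and serialises losslessly", {
  d <- make_default_design(seed = 1)
  tr <- simulate_trial(d, default_population_model(), seed = 2)
  pf <- fit_plasma(tr)
  cf <- fit_cages(tr, empirical_bayes(pf))
  tab <- parameter_table(pf, cf)
  # all estimated fixed effects, betas, omegas and error terms present
  expect_setequal(
    setdiff(tab$parameter[!tab$reference], NA),
    c("V", "k12", "beta_k12_carr_sheep", "k21", "beta_k21_carr_sheep", "CL",
      "k31", "beta_k31_side_right", "beta_k31_len", "beta_k31_carr_cage",
      "k13", "beta_k13_side_right", "beta_k13_len", "beta_k13_carr_cage",
      "omega_V", "omega_CL", "omega_k31", "omega_k13", "b_plasma", "b_cage"))
  ref <- tab[tab$reference, ]
  expect_true(all(ref$estimate == 0))
  expect_true(all(is.na(ref$ci_low)))
  expect_true(all(tab$ci_low[!tab$reference & !is.na(tab$ci_low)] <=
                    tab$estimate[!tab$reference & !is.na(tab$ci_low)]))
  # CSV round trip
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(tab, path, row.names = FALSE)
  back <- read.csv(path)
  expect_equal(back$estimate, tab$estimate, tolerance = 1e-12)
  expect_equal(back$parameter, tab$parameter)
})

test_that("Wald intervals bracket their estimates and RSEs are positive", {
  d <- make_default_design(seed = 4)
  tr <- simulate_trial(d, default_population_model(), seed = 5)
  pf <- fit_plasma(tr)
  ok <- !is.na(pf$se)
  expect_true(all(pf$ci_low[ok] <= pf$estimates[ok] + 1e-12))
  expect_true(all(pf$estimates[ok] <= pf$ci_high[ok] + 1e-12))
  expect_true(all(pf$rse_percent[ok] >= 0))
  expect_true(all(pf$p_values >= 0 & pf$p_values <= 1))
})
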