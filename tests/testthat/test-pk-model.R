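ref_plasma <- plasma_params(V = 0.0924, CL = 0.00235, k12 = 0.121, k21 = 0.200)
ref_cage <- cage_params(k13 = 0.124, k31 = 0.455)

test_that("macro-constants are the eigenvalues of the disposition matrix", {
  m <- macro_constants(ref_plasma, 4)
  # independent oracle: eigenvalues of the two-compartment rate matrix
  k10 <- ref_plasma$CL / ref_plasma$V
  A <- matrix(c(-(k10 + ref_plasma$k12), ref_plasma$k21,
                ref_plasma$k12, -ref_plasma$k21), 2, 2, byrow = TRUE)
  ev <- sort(-eigen(A)$values)
  expect_equal(m$lambda_slow, ev[1], tolerance = 1e-10)
  expect_equal(m$lambda_fast, ev[2], tolerance = 1e-10)
  expect_equal(m$lambda_slow, 0.015364, tolerance = 1e-4)
  expect_equal(m$lambda_fast, 0.331069, tolerance = 1e-4)
  expect_equal(m$coef_fast + m$coef_slow, 4 / 0.0924, tolerance = 1e-12)
})

test_that("one-compartment collapse and dose linearity of the plasma model", {
  p1 <- plasma_params(V = 0.1, CL = 0.005, k12 = 1e-12, k21 = 1e-6)
  m1 <- macro_constants(p1, 4)
  expect_equal(m1$lambda_slow, 1e-6, tolerance = 1e-3)
  p2 <- plasma_params(V = 0.1, CL = 0.005, k12 = 1e-10, k21 = 0.2)
  expect_equal(macro_constants(p2, 1)$lambda_slow, 0.05, tolerance = 1e-6)
  expect_equal(plasma_conc(ref_plasma, 4, 0), 4 / 0.0924, tolerance = 1e-12)
  t <- c(0, 0.5, 3, 24, 72)
  expect_equal(plasma_conc(ref_plasma, 8, t), 2 * plasma_conc(ref_plasma, 4, t),
               tolerance = 1e-12)
  expect_error(plasma_conc(ref_plasma, 4, -1), "non-negative")
})

test_that("closed-form plasma and cage profiles match the stiff ODE oracle", {
  t <- c(1, 8, 48)
  o <- ode_oracle(ref_plasma, ref_cage, 4, t)
  expect_equal(plasma_conc(ref_plasma, 4, t), unname(o$plasma), tolerance = 1e-8)
  expect_equal(cage_conc(ref_plasma, ref_cage, 4, t), unname(o$cage),
               tolerance = 1e-8)
  # degenerate case: k31 equal to the slow exponent
  lam <- macro_constants(ref_plasma, 4)$lambda_slow
  cg <- cage_params(k13 = 0.124, k31 = lam)
  o2 <- ode_oracle(ref_plasma, cg, 4, t)
  expect_equal(cage_conc(ref_plasma, cg, 4, t), unname(o2$cage), tolerance = 1e-8)
})

test_that("cage compartment starts empty, stays finite, and vanishes at infinity", {
  expect_equal(cage_conc(ref_plasma, ref_cage, 4, 0), 0)
  expect_lt(cage_conc(ref_plasma, ref_cage, 4, 5000), 1e-12)
  expect_true(all(is.finite(cage_conc(ref_plasma, ref_cage, 4, seq(0, 500, 0.5)))))
  # frozen-plasma steady state: with plasma pinned at C1 the linear cage ODE
  # tends to C1 * k13/k31 (checked through the one-compartment limit with a
  # near-zero elimination rate, where plasma is almost constant)
  pflat <- plasma_params(V = 0.1, CL = 1e-9, k12 = 1e-9, k21 = 1e-3)
  cg <- cage_params(k13 = 0.3, k31 = 0.6)
  expect_equal(cage_conc(pflat, cg, 4, 5000) / plasma_conc(pflat, 4, 5000),
               0.3 / 0.6, tolerance = 1e-4)
})

test_that("cage peak time maximises the profile and moves earlier as k31 grows", {
  tm <- cage_tmax(ref_plasma, ref_cage, 4)
  grid <- seq(0, 200, by = 0.05)
  expect_gte(cage_conc(ref_plasma, ref_cage, 4, tm) + 1e-12,
             max(cage_conc(ref_plasma, ref_cage, 4, grid)))
  k31s <- c(0.02, 0.05, 0.1, 0.2, 0.455, 1, 3, 10)
  tms <- vapply(k31s, function(k31)
    cage_tmax(ref_plasma, cage_params(0.124, k31), 4), numeric(1))
  expect_true(all(diff(tms) < 1e-8))
  # grid-search oracle for one value
  expect_equal(tms[3], grid[which.max(cage_conc(ref_plasma, cage_params(0.124, 0.1),
                                                4, grid))], tolerance = 0.05)
  # quasi-equilibrium limit: very fast exchange peaks essentially at dosing
  expect_lt(cage_tmax(ref_plasma, cage_params(0.124, 500), 4), 0.05)
})

test_that("half-life arithmetic matches the published spot values", {
  expect_equal(signif(half_life_from_rate(0.0400), 3), 17.3)
  expect_equal(signif(half_life_from_rate(0.1060), 3), 6.54)
  expect_equal(half_life_from_rate(log(2)), 1)
  expect_error(half_life_from_rate(0), "positive")
  expect_error(half_life_from_rate(-1), "positive")
})

test_that("published rate/half-life table cells are near-consistent with ln2/k", {
  # the printed half-lives were computed from unrounded rate constants before
  # the k column was rounded, so a minority of cells drift by a final-digit
  # unit or two; ln2/k of the printed k must stay within 1% of every printed
  # half-life, and most cells reproduce exactly at 3 significant figures
  tab5 <- local({
    k13 <- rbind(c(0.0581, 0.1060, 0.221, 3.14, 6.54, 11.90),
                 c(0.0530, 0.1140, 0.197, 3.52, 6.06, 13.10),
                 c(0.0267, 0.0862, 0.158, 4.39, 8.03, 26.00),
                 c(0.0248, 0.0582, 0.178, 3.89, 11.90, 27.90),
                 c(0.0234, 0.0694, 0.229, 3.03, 9.98, 29.60))
    k31 <- rbind(c(0.2060, 0.3860, 0.644, 1.08, 1.80, 3.36),
                 c(0.1000, 0.1530, 0.341, 2.03, 4.54, 6.93),
                 c(0.0420, 0.0703, 0.173, 4.00, 9.86, 16.50),
                 c(0.0284, 0.0513, 0.111, 6.27, 13.50, 24.40),
                 c(0.0161, 0.0400, 0.107, 6.48, 17.30, 43.00))
    rbind(k13, k31)
  })
  k <- t(apply(tab5[, 1:3], 1, rev))  # min t pairs with max k and vice versa
  t_printed <- tab5[, 4:6]
  t_computed <- half_life_from_rate(k)
  expect_true(all(abs(t_computed - t_printed) / t_printed < 0.01))
  expect_equal(sum(signif(t_computed, 3) == t_printed), 23)
})

test_that("terminal half-life follows the slow exponent and ignores dose", {
  expect_equal(terminal_half_life(ref_plasma),
               log(2) / macro_constants(ref_plasma, 1)$lambda_slow)
  expect_equal(terminal_half_life(ref_plasma), 45.1, tolerance = 0.01)
  p1 <- plasma_params(V = 0.1, CL = 0.005, k12 = 1e-10, k21 = 1)
  expect_equal(terminal_half_life(p1), log(2) / 0.05, tolerance = 1e-4)
})

test_that("log-linear covariates scale the typical rates as specified", {
  m <- default_population_model()
  # identity at reference levels and zero length
  ref <- apply_covariates(m, 0)
  expect_equal(ref$cage$k13, 0.124)
  expect_equal(ref$cage$k31, 0.455)
  expect_equal(ref$plasma$k12, 0.121)
  # hand arithmetic under the log-linear convention
  at3 <- apply_covariates(m, 3)
  expect_equal(at3$cage$k31, 0.455 * exp(-0.441), tolerance = 1e-12)
  at18 <- apply_covariates(m, 18)
  expect_equal(at18$cage$k13, 0.124 * exp(-0.0378 * 18), tolerance = 1e-12)
  # carrageenan in sheep moves k21, not V or CL
  carr <- apply_covariates(m, 3, carr_sheep = TRUE)
  expect_equal(carr$plasma$k21, 0.200 * exp(0.336), tolerance = 1e-12)
  expect_equal(carr$plasma$V, 0.0924)
  # all-zero effects give the identity transform
  m0 <- m; m0$covariates <- covariate_effects()
  id <- apply_covariates(m0, 18, TRUE, TRUE, TRUE)
  expect_equal(id$cage$k13, 0.124)
  expect_equal(id$plasma$k21, 0.200)
})

test_that("individual draws follow the lognormal random-effect model", {
  m <- default_population_model()
  m0 <- m; m0$omegas <- random_effect_sds()
  d1 <- draw_individual(m0, 3, seed = 1)
  expect_equal(d1$plasma$V, apply_covariates(m, 3)$plasma$V)
  expect_equal(d1$cage$k13, apply_covariates(m, 3)$cage$k13)
  # same seed reproduces the draw exactly
  expect_identical(draw_individual(m, 3, seed = 7), draw_individual(m, 3, seed = 7))
  # Monte-Carlo check of the log-scale SD of clearance
  set.seed(42)
  cls <- replicate(10000, draw_individual(m, 3)$plasma$CL)
  expect_equal(sd(log(cls)), 0.448, tolerance = 0.05)
})

test_that("model YAML serialisation round-trips", {
  m <- default_population_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  m2 <- read_model_yaml(path)
  expect_equal(unclass(m2$plasma), unclass(m$plasma), tolerance = 1e-12)
  expect_equal(unclass(m2$covariates), unclass(m$covariates), tolerance = 1e-12)
  expect_equal(m2$dose_mg_per_kg, 4)
})
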