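---
title: "Modelling drug kinetics and prostaglandin suppression in tissue cages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling drug kinetics and prostaglandin suppression in tissue cages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagepk)
```

## The tissue-cage system

A tissue cage is a perforated silicone cylinder implanted subcutaneously.
After implantation it fills with fluid that exchanges solutes with the
surrounding tissue through the punched fenestrations, so sampling the cage by
needle gives a repeated, minimally invasive window on drug concentrations
outside the bloodstream. `cagepk` models a cross-over experiment in sheep:
ten cages per animal (five lengths, 3-18 cm, duplicated left and right),
a 4 mg/kg intravenous bolus of the NSAID carprofen at time zero in each of
two periods, and carrageenan-induced inflammation of all five cages on one
randomised side during one period.

Because every cage carries the same 24 holes of 4 mm diameter, the diffusible
area is fixed (`fenestration_area()`, 3.0159 cm^2) while the lumen volume
grows with length, so the surface-area-to-volume ratio (SA/V) falls from
0.5689 cm^-1 (3 cm) to 0.0948 cm^-1 (18 cm). Under Fick's law the transfer
rate constants of a cage scale with SA/V times a permeability constant
(`fick_rate()`), which is why cage length is the design's lever on kinetics.
The tubing wall is taken as 1 mm (15 mm lumen from 17 mm OD tubing): that is
the only wall thickness consistent with the published volumes, and it is kept
as an overridable default of `cage_spec()`. Punch holes are treated as flat
circles, and the lumen volume is the full nominal cylinder (the putty-sealed
ends are not subtracted) — both choices match the published geometry table
exactly.

## The pharmacokinetic model

Plasma disposition is a standard two-compartment IV-bolus model,
parameterised by central volume $V$, clearance $CL$ (elimination rate
$k_{10}=CL/V$) and transfer rates $k_{12}, k_{21}$. The concentration is the
biexponential $C_1(t) = A e^{-\alpha t} + B e^{-\beta t}$ with
$\alpha, \beta$ the roots of $\lambda^2 -(k_{10}+k_{12}+k_{21})\lambda +
k_{10}k_{21} = 0$ (`macro_constants()`).

Each cage is a *forcing-function* compartment: its fluid concentration obeys

$$\frac{dC_3}{dt} = k_{13}\,C_1(t) - k_{31}\,C_3, \qquad C_3(0)=0,$$

with no feedback on plasma — the drug mass entering all ten cages is
negligible relative to the body. The closed form is a sum of
$(e^{-\lambda t} - e^{-k_{31} t})/(k_{31}-\lambda)$ terms, evaluated through
`expm1` so that it stays accurate through the degeneracy $k_{31} \approx
\lambda$; only an exact tie (relative difference below $10^{-12}$) switches
to the $t\,e^{-\lambda t}$ limit. The closed forms are validated against a
stiff ODE integrator to a relative error of $10^{-8}$ over a grid of more
than one hundred parameter sets, including the degenerate ties.

Covariates act log-linearly and uncentered:
$\log k = \log k_{\mathrm{pop}} + \sum_j \beta_j x_j$, with cage length in cm
and 0/1 flags for carrageenan-in-cage, carrageenan-in-sheep (on
$k_{12},k_{21}$) and right side; left side without carrageenan is the
reference. The uncentered log-linear convention is a deliberate choice: with
the reference length effect $\beta_{k_{31},\mathrm{len}} = -0.147$ per cm it
predicts an 18 cm/3 cm typical-$k_{31}$ ratio of $e^{-0.147\cdot 15} \approx
0.11$, matching the observed ratio of the per-size median individual
estimates ($0.0400/0.386 \approx 0.104$), which neither an additive nor a
centered convention reproduces.

Between-animal variability is lognormal on $V$ and $CL$ (one shared pair of
random effects per sheep, both periods), and between-cage variability is
lognormal on $k_{13}$ and $k_{31}$ (independent pair per cage, shared across
periods). $k_{12}$ and $k_{21}$ carry no random effects because no
variability was reported for them. Random effects are placed per cage rather
than per sheep-side because each animal contributes ten cages with clearly
distinct individual rate estimates. Residual error is proportional,
$y = f(1 + b\,\varepsilon)$, with separate coefficients for plasma
($b_1 = 0.136$) and cage fluid ($b_2 = 0.468$).

`default_population_model()` carries the full reference parameter set
(typical values, covariate effects, random-effect SDs, error coefficients,
4 mg/kg dose). One knowingly unresolved inconsistency of that source set:
its two-compartment population values imply a terminal half-life of
$\ln 2/\beta \approx 45$ h (`terminal_half_life()`), while the reported
terminal half-life is 27.2 h, presumably derived from individual estimates
or non-compartmental analysis; the package computes the closed form and does
not attempt to reproduce the 27.2 h figure. Similarly, the published
per-size rate-constant table rounds its $k$ and $t_{1/2}$ columns
independently, so seven of its thirty printed half-life cells are not
exactly $\ln 2/k$ of the printed rate at three significant figures; the
package verifies consistency within the rounding interval of the printed
rates instead.

## The trial simulator

`simulate_trial()` generates the full cross-over design: 7 sheep by default,
two periods, sampling at $-1, 0.5, 1, \dots, 72$ h, carrageenan in all five
cages of one randomised side in period 2. Pre-dose ($-1$ h) samples are
recorded as zero concentration, flagged, and excluded from every fit — the
handling of assayed pre-dose samples was never specified, and for an IV
bolus of a drug absent at baseline they carry no kinetic information.
Proportional-error draws that fall below zero are truncated at zero (about
1.5% of cage records at the reference error level; the count is attached to
the returned data frame). Missingness is off by default and available as a
uniform-at-random drop rate for cage records, mirroring the occasional lost
series in the real study. Body weight is absorbed into per-kg units, so
doses are mg/kg and volumes L/kg, giving concentrations in ug/mL.

What the generator deliberately does not emulate: assay quantification
limits and censoring, enterohepatic recirculation (visible in the real
plasma data but excluded from the model), enantiomer-specific kinetics, and
protein binding. Passing recovery tests therefore shows that the estimation
machinery is consistent with its own generating model at the study's design
size — not that the model captures every feature of real sheep data.

## Sequential estimation

The fitting strategy mirrors the original two-stage analysis: the plasma
model is fitted first, on plasma data alone (`fit_plasma()`); each sheep's
individual $(V, CL)$ are then set to their empirical-Bayes modes
(`empirical_bayes()`); and the cage model is fitted with each sheep-period
plasma curve fixed as a forcing function (`fit_cages()`). A joint refit of
both stages is intentionally out of scope.

Both stages maximise a Laplace-approximated marginal likelihood. The inner
step finds the penalised posterior mode of the two random effects of every
group by a damped, step-capped Newton iteration run vectorised across all
groups simultaneously; the outer step is quasi-Newton (`nlminb`) on
log-transformed parameters (positivity by construction), with random-effect
SDs bounded below at $10^{-6}$. The cage stage uses exact analytic inner
gradients and Hessians; the plasma stage uses central finite differences.
The Laplace approximation is checked against adaptive Gauss-Hermite
quadrature (9 nodes) on one-random-effect problems, agreeing well within 0.5
log-units. The original analysis used stochastic-approximation EM; that
optimiser is not re-implemented — the model, not the optimiser, is the
scientific content, and on simulated data the Laplace fits recover the
generating values.

Starting values are data-driven but crude: a dose-over-peak volume and
terminal-slope clearance for plasma, and a per-series profiled log-scale
least-squares scan over $k_{31}$ (with $k_{13}$ concentrated out, since the
cage profile is linear in $k_{13}$) followed by an OLS regression of the
per-series log rates on the covariates for the cage stage. Standard errors
are Wald, from a numerical Hessian of the outer objective, with the delta
method mapping log-scale SEs to the natural scale; p-values are reported for
covariate effects only, matching the original presentation. Covariate
effects whose covariate does not vary in the supplied data are dropped with
a warning rather than left unidentifiable.

Convergence uses `nlminb`'s relative-objective and parameter-change
criteria (defaults $10^{-8}$ and $10^{-6}$, configurable via
`fit_control()`); because the warm-started inner solve can leave
sub-tolerance noise, an optimiser report of "false convergence" is accepted
when the outer gradient is numerically flat at the optimum, and a stalled
run is restarted from its end point (up to three times) while that still
improves the objective. One degenerate regime deserves note: with exactly
zero residual error the proportional-error likelihood is unbounded (the
error coefficient runs to its floor and the surface collapses into a
needle), so the noise-free exact-data limit is validated at a tiny positive
error level (0.5%), where sampling error sits far below the recovery
tolerance. The replicate
recovery studies (`recovery_study()`) relax the outer tolerances to
$10^{-6}$/$10^{-4}$ and the inner gradient tolerance to $10^{-7}$, which
changes the recovered values by well under a tenth of a percent while
roughly halving the fit time.

## Peak summaries and contrasts

`observed_peaks()` extracts the observed $C_{max}$ and $T_{max}$ per cage
series, breaking ties toward the earliest attaining time (the original
convention is unstated; earliest is reproducible and conservative for a
rising profile). `summarize_peaks()` gives per-size counts, medians and
ranges. `emm_contrasts()` fits response ~ size-factor with a random sheep
intercept (REML via `nlme`) and reports all ten pairwise differences of
estimated marginal means with Wald intervals — the model behind the original
contrast tables is unstated, so this choice is documented rather than
claimed, a fixed-effects-only fallback is available, and no multiplicity
adjustment is applied by default (a Holm option exists).

## The prostaglandin-metabolite model

The pharmacodynamic readout is a stable prostaglandin-E metabolite (PGEM) in
cage fluid. The model is linear mixed on the log10 scale:

$$\log_{10}(\mathrm{PGEM}) = \beta_0 + \gamma_{\mathrm{sheep}} +
\beta_1 t + \beta_2(\mathrm{size}) + \beta_3(\mathrm{size})\,t +
\varepsilon,$$

with cage size a five-level factor (3 cm reference), fitted by REML
(`fit_pgem_lme()`, engine `nlme::lme`). Carprofen concentration is excluded
as a predictor because it is collinear with time in this design. Time is in
hours since dose, uncentered. Fit quality is summarised by Nakagawa's
marginal and conditional R-squared (`nakagawa_r2()`), computed from the
variance of the fixed-effect predictor over the data.

The generating variance components for simulation are not part of the
published coefficient table; they are recovered from the published
R-squared pair (0.27 marginal, 0.42 conditional) by inverting the Nakagawa
definitions (`solve_variance_components()`) with the fixed-effect variance
computed over the sampling layout — the only self-consistent choice given
what was reported. The simulated layout samples the five inflamed-side cages
of each sheep at six times (0.5, 6, 12, 24, 48, 72 h) and thins the
non-inflamed side to an inclusion probability of 74/210, reproducing the
reported imbalance of roughly 205 inflamed versus 74 non-inflamed records
(~280 total).

## Problem sizes and what the checks mean

The package's validation works at these scales, chosen to give clear
signal-to-noise for each claim: geometry and half-life arithmetic are exact;
closed forms are checked against the ODE oracle on a 192-point parameter
grid; PK recovery uses 20 replicate 50-sheep trials (replicate mean within
three simulation standard errors of the generating value) plus 100 replicate
7-sheep trials for median bias (within 10% for $V$ and $CL$) and Wald
coverage (observed 0.86-0.88 for nominal 95% at 7 sheep — mild small-sample
undercoverage, inside the 0.85-0.99 band the recovery suite enforces); PGEM
recovery uses 20 replicate ~280-record datasets. `scripts/acceptance.R`
re-runs the simulate-and-refit studies from scratch at these sizes.

## Known limitations

* Sequential (conditional) fitting propagates no plasma-stage uncertainty
  into the cage stage; cage-stage SEs are conditional on the individual
  plasma curves.
* Laplace marginal likelihood is an approximation; with only 7 subjects the
  random-effect SDs are noisy and Wald intervals undercover slightly.
* The EMM-contrast and PGEM p-values use Wald/containment degrees of
  freedom, which may differ from whatever the original analysis used.
* The simulator shares the model's assumptions (no recirculation, no
  censoring), so recovery results validate internal consistency, not
  biological fidelity.
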