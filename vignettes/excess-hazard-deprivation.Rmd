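---
title: "Modelling deprivation gradients in cancer net survival with penalized excess-hazard regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling deprivation gradients in cancer net survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

Cancer registries record dates of diagnosis and death but rarely a reliable
cause of death. Net survival — survival from the cancer itself, as if other
causes of death were removed — is therefore estimated through the *excess
mortality hazard* framework. The observed mortality hazard of a patient at
time `t` since diagnosis, age `a` at diagnosis and deprivation score `EDI`
is decomposed as

    h(t, a, EDI, z) = hE(t, a, EDI) + hP(a + t, z),

where `hP` is the all-cause mortality hazard of the general population
matched on demographics `z` (sex, calendar year during follow-up, region),
read from national life tables, and `hE` is the excess hazard attributable,
directly or indirectly, to the cancer. Net survival at covariate profile
`(a, EDI)` is `S_N(t) = exp(-∫₀ᵗ hE(u, a, EDI) du)`.

Deprivation is measured by the European Deprivation Index (EDI), a
continuous, right-skewed area-level score (higher = more deprived), and
patients are grouped into national quintiles Q1 (least deprived) to Q5
(most deprived). Effects are summarised as *excess hazard ratios* (EHR)
between the median EDI of each quintile (`mQ1 = -4.2`, `mQ2 = -2.4`,
`mQ3 = -0.9`, `mQ4 = 0.8`, `mQ5 = 5.1`) and `mQ1`, evaluated at a reference
age of 70 years.

## Model family

The log excess hazard is modelled with restricted cubic splines and
penalized tensor products, in four nested structures:

* `M0`: `log hE = tensor(t, a)` — no deprivation effect;
* `M1`: `log hE = tensor(t, a) + s(EDI)` — a (possibly non-linear)
  deprivation effect, constant over follow-up time and age;
* `M1b`: `log hE = tensor(t, a) + s(EDI) + tint(t, EDI)` — a time-dependent
  deprivation effect (`tint` is a tensor containing interaction terms only);
* `M2`: `log hE = tensor(t, a, EDI)` — a fully time- and age-dependent
  deprivation effect.

Knots (6 for time, 5 for age, 5 for EDI by default) are placed at equally
spaced percentiles of each variable **among the deceased**, the subset that
carries the information in an excess-hazard likelihood.

### Basis and penalty construction

One-dimensional smooths use the truncated-power natural cubic (restricted)
parameterization: with `k` knots the raw basis is
`1, x, N_1(x), …, N_{k-2}(x)`, linear beyond the boundary knots. Non-constant
columns are centred and scaled using a fixed 201-point uniform grid over the
knot range, so every basis is a reproducible function of the knots alone.
The curvature penalty `∫ f''(x)² dx` is integrated exactly (second
derivatives are piecewise linear, so Simpson's rule per knot interval is
exact).

Tensor products are row-wise Kronecker products of the full marginal bases
(time index fastest, then age, then EDI), with one penalty per margin built
as the marginal curvature penalty crossed with identities. Because each
marginal basis carries an explicit constant column, the pure-constant tensor
column *is* the global intercept and no further identifiability constraint
is needed; the `s(EDI)` and `tint` blocks are built from the non-constant
(grid-centred) columns only, so they contain no constant and no marginal
main effects — every `tint` column averages to zero over the marginal
reference grid, which is the functional-ANOVA sense in which it is
"interaction only".

`M1b` carries five smoothing parameters by default (two for `tensor(t,a)`,
one for `s(EDI)`, two for `tint` — one per direction; a single-λ variant is
available via `tint_two_lambdas = FALSE`). This follows the convention of
multidimensional penalized-spline survival software; how many smoothing
parameters the interaction tensor should carry is genuinely open, and the
two-λ default is the more flexible choice.

### Estimation

The full likelihood uses the background hazard as a known offset at event
times; the background cumulative hazard contains no parameters and is
dropped:

    l(β) = Σᵢ [ δᵢ log(hE(tᵢ) + hPᵢ) − ΛE,ᵢ ] ,
    lp(β) = l(β) − ½ Σⱼ λⱼ βᵀSⱼβ .

`ΛE,ᵢ` is computed by Gauss–Legendre quadrature (20 nodes per subject by
default, near machine precision for smooth log-hazards; 10 nodes are used in
the large replicate studies below, where the quadrature error is orders of
magnitude below the Monte-Carlo noise). Coefficients are estimated by
Newton–Raphson with step halving (gradient max-norm `1e-6`, relative change
`1e-9`); smoothing parameters by maximizing the Laplace approximate marginal
likelihood

    LAML(λ) = lp(β̂λ) + ½ log|S_λ|₊ − ½ log|Hp(β̂λ)| + (Mp/2) log 2π ,

with `|·|₊` the generalized determinant over the penalized subspace, `Hp`
the negative penalized Hessian and `Mp` the penalty null-space dimension.

Two numerical choices matter here. First, `log|S_λ|₊` is computed block-wise
(the penalties are block-diagonal by model term) with a *fixed* rank per
block, established once at λ = 1. A tolerance-based rank recomputed at each
λ silently drops directions once smoothing parameters differ by many orders
of magnitude, which removes the barrier that stops λ from collapsing to 0 —
a failure mode we observed and designed out. Second, the outer optimization
(Nelder–Mead over log λ; Brent for a single penalty) is confined to
`|log λ| ≤ 12`, which keeps within-block eigenvalue ratios resolvable in
double precision. The outer search is multistarted from all penalties at 0.1
and all at 10 — two vector starts rather than the 2^d corner grid, which
would be prohibitive for the 5-penalty `M1b` and adds nothing for a smooth,
essentially unimodal criterion.

Structures are compared by corrected AIC on the *unpenalized* log-likelihood
at the penalized estimate, with effective degrees of freedom
`EDF = tr(Hp⁻¹ H)`:

    AICc = −2 l(β̂) + 2 EDF + 2 EDF (EDF + 1) / (n_events − EDF − 1) .

The number of events is used as the effective sample size — events carry the
information in survival likelihoods. Which "corrected AIC" variant the
methodology literature intends is ambiguous (the small-sample AICc versus a
smoothing-uncertainty-corrected criterion); both the AICc above and plain
`−2l + 2·EDF` are implemented (`aic = "plain"`), with AICc the default.
Exact criterion ties resolve to the simpler structure (M0 < M1 < M1b < M2).

Confidence intervals are Wald at 95% (`z = 1.959964`) using the posterior
covariance `Hp⁻¹`: on the log scale for EHRs, on the log-cumulative-hazard
scale for net survival. Smoothing-parameter uncertainty is not propagated;
CIs for EHRs could alternatively be simulated from the posterior, but the
delta method is the default as the simpler, standard choice.

## The non-parametric benchmark

The Pohar-Perme estimator weights each subject's counting processes by the
inverse of their expected survival `1/S_P(t)`. We use the product-limit form

    S_N(t) = Π_{s≤t} (1 − dN^w(s)/Y^w(s)) · exp(+∫₀ᵗ λ_P^w(u) du) ,

which reduces *exactly* to Kaplan–Meier when `hP ≡ 0` (the exponential form
of the jump part would not). The population term is integrated on
sub-intervals between observed times (half-month cap), exactly for tables
that are constant over the interval. Model adequacy is assessed by
overlaying the *population-averaged* model curve — the mean of individual
predicted `S_N` over the cohort — since Pohar-Perme is a marginal estimator.

## The synthetic registry and what it does (not) show

No patient-level registry data are distributable, so every downstream stage
is exercised on synthetic cohorts with known truth:

* diagnoses uniform over 2006–2009, administrative censoring 30 June 2013,
  2% uniform loss to follow-up; survival times of exactly zero are set to
  half a day;
* age at diagnosis truncated-normal (mean 71, sd 11, range 18–99), matching
  the median ages of digestive-cancer registries (66–77);
* EDI from a shifted log-normal `exp(N(log(22/3), 0.4664)) − (22/3 + 0.9)`,
  truncated at 56. The three parameters were solved from three constraints —
  national median −0.9 and 10th/90th percentiles −4.2 / 5.1 (the reference
  quintile-median anchors) — giving quintile medians (−4.2, −2.5, −0.9, 1.1,
  5.1) and support within [−16, 56]. The within-quintile distribution of
  real EDI is not published; this law is a stand-in with the right median,
  spread and skew, not an estimate;
* national quintile boundaries computed from the law itself (not from the
  cohort), mirroring how national quintiles are defined;
* baseline excess hazard Weibull (scale 6.76, shape 0.75: decreasing, ~45%
  net survival at 5 years, typical of mid-prognosis digestive cancers), a
  log-linear age effect of 0.02/year, and a deprivation effect that is
  null, proportional (`β = 0.024` per EDI unit, EHR mQ5 vs mQ1 = 1.25) or
  time-dependent (`β(t) = −0.02 + 0.12 e^{−t}` per EDI unit: strong early
  effect fading and slightly reversing, the pattern reported for stomach and
  colon cancers in females);
* background mortality from a Gompertz-shaped synthetic national life table
  (`3.7e-5 · e^{0.09·age}`, female advantage 0.55, 1% annual decline).

Event times are drawn by numerical inversion of the total cumulative hazard
on a daily grid (midpoint rule, linear interpolation within the crossing
day), implemented in a small compiled kernel; the inversion is exact for the
piecewise-constant background and accurate to well below a day for the
smooth excess hazard.

Passing tests on these cohorts demonstrate that the estimation machinery
recovers known truths under correct specification and realistic censoring.
They do not validate the proportional-hazards-like structure against real
registries, the EDI measurement process, or life-table misclassification —
real analyses inherit those on top of what is tested here.

## Simulation studies and their problem sizes

The replicated studies use sizes chosen to keep Monte-Carlo error small
relative to the tested margins:

* *Parameter recovery*: 200 replicates of n = 2000 proportional-effect
  cohorts, fitted as M1 with the 6/5/5 analysis knots; the mean EHR(mQ5 vs
  mQ1) must lie in [1.20, 1.30] (truth 1.25) and empirical 95% CI coverage
  in [0.90, 0.98].
* *Structure selection*: 100 replicates each of null and strongly
  time-dependent scenarios at n = 1500, all four structures fitted. These
  fits use 4/3/3 knots — a model-side choice appropriate to n = 1500
  replicate cohorts (about 5 events per parameter for the largest
  candidate); the selection mechanics are identical at any basis size.
* *Sensitivity mechanism*: the deprivation gradient is planted entirely in
  background mortality (quintile rate ratios 0.6/0.8/1.0/1.3/1.8, the
  "extreme correction" magnitude of published deprivation-specific life
  tables), with no excess-hazard effect, in an older cohort (mean age 75)
  with a more indolent cancer (Weibull scale 8.5) where background mortality
  is a substantial share of total mortality. Analysing with the common table
  must then show a spurious EHR > 1 that the quintile-matched tables pull
  back toward 1 — in at least 80% of 100 replicates of n = 3500.

Replicate fits use a single outer start (λ = 1) and a coarse outer tolerance
(`reltol 1e-3`, ≤ 40 Nelder–Mead iterations): point estimates and selection
are insensitive to smoothing-parameter error at that scale, and the full
two-start search is reserved for one-shot analyses.

## Degenerate inputs and edge policies

* Life-table lookups floor age and year to 1-year Lexis cells and clamp at
  the declared edges, so patients older than the last age band use the edge
  cell rather than being discarded; missing sex/region strata raise coverage
  errors.
* Calendar year during follow-up is the time-updated year (diagnosis decimal
  year + t), so `hP` is evaluable at every `t`, not only at death.
* Rate-ratio stratification is multiplicative on hazards; whether to
  renormalize so the equal-weight quintile mean preserves the base rate is
  exposed as a flag (`renormalize`), both behaviours being defensible
  readings of "applying an observed gradient to the original tables".
* Records with missing EDI are dropped (complete-case) with a logged count.
* Fewer than 3 distinct knots, non-monotone quintile boundaries, negative
  follow-up times, rank-deficient interaction tensors, and `AICc` with
  `events ≤ EDF + 1` are errors; inner-Newton non-convergence is a flagged
  result, and a structure that fails to converge is excluded from selection
  with a warning.
* Zero-length risk sets truncate the Pohar-Perme curve with a warning.

## Known limitations

* The EDI long right tail is handled by percentile knots among the deceased
  with no winsorization; predictions far beyond the last knot use the
  natural spline's linear tail (a warning is issued).
* The likelihood with `hP > 0` is not globally concave; Newton with step
  halving and ridge stabilization has been robust in all exercised regimes,
  but pathological starts can in principle stall (flagged, not silent).
* LAML is maximized over at most five smoothing parameters with numerical
  (derivative-free) search; for much larger penalty counts an analytic
  gradient scheme would be needed.
* Smoothing-parameter uncertainty is not propagated into intervals; coverage
  is calibrated in the recovery study but could degrade in regimes where λ
  is poorly identified.
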