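# netgradient

Flexible excess-hazard modelling of social deprivation gradients in cancer
net survival.

## The problem

Population-based cancer registries record diagnoses and deaths but not the
cause of death, so survival *from the cancer itself* (net survival) must be
estimated by comparing the cohort's mortality with the expected (background)
mortality of the general population. Whether — and *when* during follow-up —
socially deprived patients die faster of their cancer is a question about
the **excess mortality hazard** (EMH): the observed hazard of a patient at
time `t` since diagnosis, age `a` at diagnosis and deprivation score `EDI`
decomposes as

    h(t, a, EDI, z) = hE(t, a, EDI) + hP(a + t, z)

with `hP` the all-cause population hazard from life tables matched on
demographics `z` (sex, calendar year, region) and `hE` the excess hazard.
Net survival is `S_N(t) = exp(-∫₀ᵗ hE du)`.

This package is for biostatisticians and epidemiologists who analyse
registry cohorts in that framework. It provides:

* penalized-spline EMH regression with four nested structures for the
  deprivation effect — restricted cubic splines, tensor products and
  interaction-only tensors:

      M0:  log hE(t, a)       = tensor(t, a)
      M1:  log hE(t, a, EDI)  = tensor(t, a) + s(EDI)
      M1b: log hE(t, a, EDI)  = tensor(t, a) + s(EDI) + tint(t, EDI)
      M2:  log hE(t, a, EDI)  = tensor(t, a, EDI)

  with smoothing parameters chosen by Laplace approximate marginal
  likelihood (LAML) and structures compared by corrected AIC (M0 = no
  deprivation effect; M1 = effect constant over time and age; M1b =
  time-dependent; M2 = time- and age-dependent);
* predictions of net survival and **excess hazard ratios** (EHR) between
  national deprivation-quintile medians (mQ1 = -4.2 … mQ5 = 5.1), with
  delta-method 95% intervals;
* the Pohar-Perme non-parametric net-survival estimator and model adequacy
  checks against it;
* life-table machinery, including deprivation-stratified tables built from
  quintile mortality rate ratios for sensitivity analyses;
* a synthetic-registry generator with known true excess hazard (null,
  proportional, or time-dependent deprivation effects) so the whole chain is
  testable by parameter recovery.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Step 1
simulates registry-like cohorts (diagnoses 2006–2009, end of follow-up
30 June 2013, ~2% loss to follow-up, right-skewed EDI with national quintile
boundaries) over a synthetic national life table:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_select.R
```

```
null           selected M0  (AICc: M0=5903.1, M1=5908.0, M1b=5917.1, M2=5926.8)
proportional   selected M1  (AICc: M0=12034.8, M1=12031.4, M1b=12038.5, M2=12051.6)
time_dependent selected M1b (AICc: M0=5917.3, M1=5878.2, M1b=5865.2, M2=5873.8)
```

Selection recovers each generating structure: no EDI effect → M0; a
proportional effect → M1; a strong early effect that fades → M1b.

```sh
Rscript analysis/03_predict.R
```

```
proportional   [M1]  EHR mQ5 vs mQ1: 1.20 [1.06-1.35]
time_dependent [M1b] EHR mQ5 vs mQ1: 2.18 [1.56-3.06] @0.08y;
                     1.30 [0.99-1.72] @1.00y; 0.93 [0.59-1.47] @5.00y
```

The proportional cohort was generated with a log-EHR of 0.024 per EDI unit,
i.e. a true EHR(mQ5 vs mQ1) of exp(0.024 × 9.3) = 1.25; the fitted 1.20
[1.06–1.35] covers it. The time-dependent cohort's EHR at one month (2.18)
fading to ~1 by five years is the generating pattern. Step 4 overlays the
population-averaged model curve on the Pohar-Perme estimator (sup-distances
0.005–0.012 here), and step 5 re-runs the proportional analysis under
deprivation-specific life tables with an extreme background gradient
(quintile rate ratios 0.6–1.8):

```
selected: main = M1 ; stratified = M0
main         EHR mQ5/mQ1 = 1.197 [1.058-1.355]
sensitivity  EHR mQ5/mQ1 = 1.038 [0.915-1.178] (forced M1)
```

— the stratified tables absorb part of the gradient into background
mortality and pull the EHR toward 1, the expected behaviour of this
"extreme correction" sensitivity analysis.

Programmatic use mirrors the scripts:

```r
library(netgradient)
lt  <- synthetic_lifetable()
co  <- generate_cohort(scenario_config(n_subjects = 4000, seed = 2027,
                                       effect_kind = "proportional",
                                       beta_edi = 0.024), lt)
sel <- select_structure(co, lt)        # fits M0, M1, M1b, M2; picks by AICc
compute_ehr(sel$selected_fit, age = 70)
predict_net_survival(sel$selected_fit, age = 70, edi = -0.9,
                     time_grid = seq(0, 5, 0.1))
adequacy_check(sel$selected_fit, co, lt)
```

A single deterministic end-to-end run (tables, serialized fits, and a
machine-readable summary) is `run_analysis(run_config(...))`.

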