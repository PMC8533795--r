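# Shared fixtures, built in code. The default synthetic national life table
# is cached once per test run; fits reuse a fast-but-adequate outer control.

LT_DEFAULT <- synthetic_lifetable()

# life table with one constant rate everywhere (small ranges keep it light)
const_lifetable <- function(rate, ages = 0:110, years = 2004:2016,
                            sexes = c("female", "male"), regions = "R1") {
  g <- expand.grid(age = ages, year = years, sex = sexes, region = regions,
                   stringsAsFactors = FALSE)
  g$rate <- rate
  lifetable(g)
}

LT_ZERO <- const_lifetable(0)

# outer-optimization effort used in simulation studies (documented choice:
# coarse LAML tolerance, single start; selection and point estimates are
# insensitive to smoothing-parameter error at this scale)
CTRL_FAST <- list(outer_maxit = 40, outer_reltol = 1e-3, starts = 1)
KNOTS_SIM <- c(time = 4, age = 3, edi = 3)

# an exponential excess-hazard cohort with no background mortality and
# (optionally) no censoring
exp_cohort <- function(n, rate = 0.3, seed = 1, censor = FALSE) {
  sc <- scenario_config(
    n_subjects = n, seed = seed, effect_kind = "null",
    baseline_excess_hazard = list(scale = 1 / rate, shape = 1),
    age_effect = 0, loss_to_followup_rate = if (censor) 0.02 else 0,
    diagnosis_window = if (censor) c("2006-01-01", "2009-12-31") else
      c("2006-01-01", "2006-01-10"),
    admin_censor_date = if (censor) "2013-06-30" else "2069-12-31",
    horizon_years = if (censor) 30 else 60
  )
  generate_cohort(sc, LT_ZERO)
}

# quick proportional-effect cohort over the default background mortality
prop_cohort <- function(n = 2000, seed = 1, beta = 0.024) {
  generate_cohort(scenario_config(n_subjects = n, seed = seed,
                                  effect_kind = "proportional",
                                  beta_edi = beta), LT_DEFAULT)
}

# Kaplan-Meier step function evaluated at given times (survival package)
km_at <- function(cohort, times) {
  sf <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                          data = cohort)
  stats::approx(c(0, sf$time), c(1, sf$surv), xout = times,
                method = "constant", rule = 2)$y
}
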