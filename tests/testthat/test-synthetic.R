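test_that("zero survival times get half a day; negatives are rejected", {
  rec <- data.frame(time_years = c(0, 1, 0.003))
  out <- apply_zero_time_rule(rec)
  expect_equal(out$time_years, c(0.5 / 365.25, 1, 0.003))
  big <- data.frame(time_years = c(rep(0.7, 999), 0))
  expect_equal(sum(apply_zero_time_rule(big)$time_years !=
                     big$time_years), 1)
  expect_error(apply_zero_time_rule(data.frame(time_years = -1)), "negative")
})

test_that("quintile assignment is lower-closed with edge values upward", {
  cuts <- c(-3.0, -1.5, 0.0, 2.0)
  expect_identical(assign_quintiles(-4.2, cuts), 1L)
  expect_identical(assign_quintiles(5.1, cuts), 5L)
  expect_identical(assign_quintiles(cuts, cuts), 2:5)
  # brute-force interval scan over a grid
  x <- seq(-5, 5, by = 0.125)
  brute <- vapply(x, function(v) {
    k <- 1L
    for (b in cuts) if (v >= b) k <- k + 1L
    k
  }, integer(1))
  expect_identical(assign_quintiles(x, cuts), brute)
  expect_error(assign_quintiles(0, c(1, 1, 2, 3)), "increasing")
})

test_that("cohorts are byte-identical under a fixed seed", {
  sc <- scenario_config(n_subjects = 300, seed = 9)
  c1 <- generate_cohort(sc, LT_DEFAULT)
  c2 <- generate_cohort(sc, LT_DEFAULT)
  expect_identical(c1, c2)
  c3 <- generate_cohort(scenario_config(n_subjects = 300, seed = 10),
                        LT_DEFAULT)
  expect_false(identical(c1$time_years, c3$time_years))
})

test_that("generated cohorts look like the registry they emulate", {
  co <- generate_cohort(scenario_config(n_subjects = 4000, seed = 3),
                        LT_DEFAULT)
  expect_true(all(co$time_years >= 0.5 / 365.25))
  expect_true(all(co$diag_date >= as.Date("2006-01-01") &
                    co$diag_date <= as.Date("2009-12-31")))
  expect_true(all(co$time_years <=
                    as.numeric(as.Date("2013-06-30") - co$diag_date) /
                      365.25 + 1e-12))
  expect_true(abs(median(co$edi) - (-0.9)) < 0.35)
  expect_true(min(co$edi) > -16 && max(co$edi) <= 56)
  # national quintile medians of the EDI law close to the reference values
  e <- scenario_config()$edi_distribution
  med <- qlnorm(c(.1, .3, .5, .7, .9), e[["meanlog"]], e[["sdlog"]]) -
    e[["shift"]]
  expect_equal(med[3], -0.9, tolerance = 0.01)
  expect_equal(med[1], -4.2, tolerance = 0.15)
  expect_equal(med[5], 5.1, tolerance = 0.15)
  # quintile labels consistent with the boundaries shipped with the cohort
  b <- attr(co, "quintile_boundaries")
  expect_identical(co$edi_q, assign_quintiles(co$edi, b))
})

test_that("null scenario event times are independent of deprivation", {
  sc <- scenario_config(n_subjects = 5000, seed = 17, effect_kind = "null")
  co <- generate_cohort(sc, LT_DEFAULT)
  d <- co[co$event == 1, ]
  tau <- cor(d$time_years, d$edi, method = "kendall")
  expect_lt(abs(tau), 0.05)
})

test_that("constant excess hazard with no background gives exponential times", {
  co <- exp_cohort(10000, rate = 0.3, seed = 23)
  expect_equal(mean(co$event), 1)             # no censoring configured
  mc_se <- sd(co$time_years) / sqrt(nrow(co))
  expect_lt(abs(mean(co$time_years) - 1 / 0.3), 3 * mc_se)
})

test_that("empirical censoring fraction matches the analytic value", {
  co <- exp_cohort(8000, rate = 0.3, seed = 31, censor = TRUE)
  # with loss to follow-up L ~ U(0, t_adm) on 2% of subjects:
  # P(censored | t_adm) = (1 - p) S(t_adm) + p * E[S(min(L, t_adm))]
  t_adm <- pmin(as.numeric(as.Date("2013-06-30") - co$diag_date) / 365.25, 30)
  p <- 0.02
  s_adm <- exp(-0.3 * t_adm)
  # P(T > L, L < t_adm) + P(T > t_adm) given loss: integrate S over U(0,t_adm)
  int_s <- (1 - exp(-0.3 * t_adm)) / (0.3 * t_adm)
  p_cens <- (1 - p) * s_adm + p * int_s
  analytic <- mean(p_cens)
  mc_sd <- sqrt(analytic * (1 - analytic) / nrow(co))
  expect_lt(abs(mean(co$event == 0) - analytic), 3 * mc_sd)
})

test_that("generator and likelihood agree: truth beats perturbed truth", {
  sc <- scenario_config(n_subjects = 1500, seed = 41,
                        effect_kind = "proportional")
  co <- generate_cohort(sc, LT_DEFAULT)
  hP <- expected_hazard_along_followup(co, LT_DEFAULT, co$time_years)
  loglik_true <- function(config) {
    cum <- vapply(seq_len(nrow(co)), function(i) {
      -log(true_net_survival(config, co$time_years[i], co$age[i], co$edi[i]))
    }, numeric(1))
    hE <- true_excess_hazard(config, co$time_years, co$age, co$edi)
    sum(co$event * log(hE + hP)) - sum(cum)
  }
  ll0 <- loglik_true(sc)
  sc_beta <- sc; sc_beta$beta_edi <- 3 * sc$beta_edi
  sc_base <- sc; sc_base$baseline_excess_hazard$scale <- 1.5 * 6.76
  expect_gt(ll0, loglik_true(sc_beta))
  expect_gt(ll0, loglik_true(sc_base))
})

test_that("missing life-table strata raise coverage errors", {
  lt_f <- const_lifetable(0.01, sexes = "female")
  sc <- scenario_config(n_subjects = 50, seed = 1, sex_ratio = 0.5)
  expect_error(generate_cohort(sc, lt_f), "sex/region")
})

test_that("cohorts and scenarios round-trip through CSV / YAML", {
  sc <- scenario_config(n_subjects = 40, seed = 77,
                        effect_kind = "time_dependent")
  co <- generate_cohort(sc, LT_DEFAULT)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  co2 <- read_cohort_csv(f)
  expect_equal(co2$time_years, co$time_years)
  expect_identical(co2$diag_date, co$diag_date)
  expect_identical(co2$edi_q, co$edi_q)
  y <- tempfile(fileext = ".yaml")
  write_scenario_yaml(sc, y)
  sc2 <- read_scenario_yaml(y)
  expect_equal(sc2$edi_distribution, sc$edi_distribution)
  expect_equal(sc2$td_shape, sc$td_shape)
  expect_identical(sc2$diagnosis_window, sc$diagnosis_window)
  unlink(c(f, y))
})
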