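test_that("linear predictor evaluation matches direct design-row products", {
  co <- prop_cohort(300, seed = 2)
  spec <- model_spec_from_cohort("M1", co)
  set.seed(3)
  beta <- rnorm(spec$p, 0, 0.3)
  t <- runif(100, 0.01, 5); a <- runif(100, 40, 90); e <- runif(100, -8, 20)
  eta <- log_excess_hazard(beta, spec, t, a, e)
  X <- model_matrix(spec, t, a, e)
  expect_equal(eta, drop(X %*% beta), tolerance = 1e-12)
  expect_error(log_excess_hazard(beta[-1], spec, t, a, e), "mismatch")
  # zero coefficients: hE = 1 per year everywhere
  expect_equal(log_excess_hazard(rep(0, spec$p), spec, 1:3, 70, 0),
               rep(0, 3))
})

test_that("M1 log excess hazard differences are free of time and age", {
  co <- prop_cohort(300, seed = 2)
  spec <- model_spec_from_cohort("M1", co)
  set.seed(4)
  beta <- rnorm(spec$p, 0, 0.3)
  d1 <- log_excess_hazard(beta, spec, 0.5, 60, 5.1) -
    log_excess_hazard(beta, spec, 0.5, 60, -4.2)
  d2 <- log_excess_hazard(beta, spec, 4.2, 83, 5.1) -
    log_excess_hazard(beta, spec, 4.2, 83, -4.2)
  expect_equal(d1, d2, tolerance = 1e-10)
})

test_that("cumulative excess hazard quadrature is exact where it should be", {
  spec_c <- model_spec("constant")
  # constant hazard 0.2 over 5 years
  expect_equal(cumulative_excess_hazard(log(0.2), spec_c, 5, 70), 1,
               tolerance = 1e-12)
  expect_error(cumulative_excess_hazard(log(0.2), spec_c, 5, 70, n_nodes = 5),
               "at least 10")
  # linear hazard h(t) = 2t via the package quadrature rule: exact
  gl <- netgradient:::gauss_legendre(20)
  tt <- 3.7
  expect_equal(sum(tt / 2 * gl$weights * 2 * (tt / 2 * (gl$nodes + 1))),
               tt^2, tolerance = 1e-12)
  # monotone in the upper limit for a fitted-style log hazard
  co <- prop_cohort(300, seed = 6)
  spec <- model_spec_from_cohort("M1", co)
  set.seed(5)
  beta <- rnorm(spec$p, 0, 0.2)
  tg <- seq(0.1, 5, by = 0.1)
  Lam <- cumulative_excess_hazard(beta, spec, tg, 70, 0)
  expect_true(all(diff(Lam) > 0))
})

test_that("log-quadratic hazards integrate to 1e-8 against a dense trapezoid", {
  gl <- netgradient:::gauss_legendre(20)
  h <- function(u) exp(0.1 + 0.35 * u - 0.06 * u^2)
  for (tt in c(0.5, 2, 5)) {
    got <- sum(tt / 2 * gl$weights * h(tt / 2 * (gl$nodes + 1)))
    u <- seq(0, tt, length.out = 20001)
    trap <- sum((h(u)[-1] + h(u)[-20001]) / 2) * diff(u)[1]
    expect_equal(got, trap, tolerance = 1e-8)
  }
})

test_that("penalized likelihood reduces to the exponential model when hP = 0", {
  co <- exp_cohort(400, rate = 0.3, seed = 11, censor = TRUE)
  spec <- model_spec("constant")
  prep <- prep_likelihood(spec, co, LT_ZERO)
  d <- sum(co$event); Tt <- sum(co$time_years)
  for (lam in c(log(d / Tt), -0.5, 0.1)) {
    got <- penalized_log_likelihood(lam, numeric(0), prep = prep)
    expect_equal(got$value, d * lam - exp(lam) * Tt, tolerance = 1e-10)
  }
})

test_that("analytic gradient and Hessian match central finite differences", {
  co <- prop_cohort(200, seed = 13)
  spec <- model_spec_from_cohort("M1", co, k = c(time = 4, age = 3, edi = 3),
                                 n_nodes = 12)
  prep <- prep_likelihood(spec, co, LT_DEFAULT)
  set.seed(14)
  lambda <- exp(runif(3, -1, 3))
  beta <- rnorm(spec$p, 0, 0.2); beta[1] <- -1
  got <- penalized_log_likelihood(beta, lambda, prep = prep)
  h <- 1e-5
  fd_grad <- vapply(seq_len(spec$p), function(j) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (penalized_log_likelihood(bp, lambda, prep = prep)$value -
       penalized_log_likelihood(bm, lambda, prep = prep)$value) / (2 * h)
  }, numeric(1))
  scale <- max(abs(got$gradient))
  expect_lt(max(abs(got$gradient - fd_grad)) / scale, 1e-5)
  fd_hess <- vapply(seq_len(spec$p), function(j) {
    bp <- beta; bp[j] <- bp[j] + h
    bm <- beta; bm[j] <- bm[j] - h
    (penalized_log_likelihood(bp, lambda, prep = prep)$gradient -
       penalized_log_likelihood(bm, lambda, prep = prep)$gradient) / (2 * h)
  }, numeric(spec$p))
  expect_lt(max(abs(got$hessian - fd_hess)) / max(abs(got$hessian)), 1e-5)
})

test_that("with no background mortality the likelihood is concave", {
  co <- exp_cohort(300, rate = 0.4, seed = 15, censor = TRUE)
  spec <- model_spec_from_cohort("M0", co, k = c(time = 4, age = 3, edi = 3))
  prep <- prep_likelihood(spec, co, LT_ZERO)
  set.seed(16)
  for (r in 1:10) {
    beta <- rnorm(spec$p, 0, 0.4)
    H <- penalized_log_likelihood(beta, c(1, 1), prep = prep)$hessian
    expect_lt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              1e-8)
  }
})

test_that("inner Newton recovers the closed-form exponential MLE", {
  co <- exp_cohort(500, rate = 0.3, seed = 17, censor = TRUE)
  spec <- model_spec("constant")
  prep <- prep_likelihood(spec, co, LT_ZERO)
  d <- sum(co$event); Tt <- sum(co$time_years)
  fit <- fit_inner(numeric(0), prep = prep, beta_init = 0.5)
  expect_true(fit$converged)
  expect_equal(fit$beta, log(d / Tt), tolerance = 1e-8)
  # restarting at the optimum converges immediately
  again <- fit_inner(numeric(0), prep = prep, beta_init = fit$beta)
  expect_lte(again$iterations, 2)
  # different initializations agree
  alt <- fit_inner(numeric(0), prep = prep, beta_init = -3)
  expect_equal(alt$beta, fit$beta, tolerance = 1e-6)
})

test_that("penalized fits from different starts coincide on real models", {
  co <- prop_cohort(400, seed = 18)
  spec <- model_spec_from_cohort("M1", co, k = c(time = 4, age = 3, edi = 3),
                                 n_nodes = 10)
  prep <- prep_likelihood(spec, co, LT_DEFAULT)
  lam <- c(5, 5, 5)
  f1 <- fit_inner(lam, prep = prep)
  f2 <- fit_inner(lam, prep = prep, beta_init = rnorm(spec$p, 0, 0.1))
  expect_true(f1$converged && f2$converged)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("LAML determinant term scales exactly with the smoothing level", {
  co <- prop_cohort(300, seed = 19)
  spec <- model_spec_from_cohort("M1", co, k = c(time = 4, age = 3, edi = 3),
                                 n_nodes = 10)
  prep <- prep_likelihood(spec, co, LT_DEFAULT)
  lam <- c(1e6, 1e6, 1e6)
  r1 <- laml(lam, prep = prep)
  r2 <- laml(2 * lam, prep = prep)
  rank_total <- spec$p - r1$null_dim
  expect_equal(r2$logdet_S - r1$logdet_S, rank_total * log(2),
               tolerance = 1e-8)
  # dual-algorithm check at moderate smoothing: block-wise generalized
  # determinant equals an eigendecomposition of the full summed penalty
  lam2 <- c(2, 5, 1)
  r3 <- laml(lam2, prep = prep)
  S <- Reduce(`+`, Map(`*`, lam2, model_penalties(spec)))
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)[seq_len(rank_total)]
  expect_equal(r3$logdet_S, sum(log(ev)), tolerance = 1e-8)
})

test_that("on data with no deprivation effect, LAML prefers heavy EDI smoothing", {
  wins <- 0
  for (r in 1:10) {
    co <- generate_cohort(scenario_config(n_subjects = 400, seed = 600 + r,
                                          effect_kind = "null"), LT_DEFAULT)
    spec <- model_spec_from_cohort("M1", co, k = c(time = 4, age = 3, edi = 4),
                                   n_nodes = 10)
    prep <- prep_likelihood(spec, co, LT_DEFAULT)
    lo <- laml(c(1, 1, 0.1), prep = prep)$laml
    hi <- laml(c(1, 1, 1e4), prep = prep)$laml
    if (hi >= lo) wins <- wins + 1
  }
  expect_gte(wins, 9)
})

test_that("LAML-optimized fits are self-consistent and EDF-bounded", {
  co <- prop_cohort(600, seed = 20)
  spec <- model_spec_from_cohort("M0", co, k = c(time = 4, age = 3, edi = 3),
                                 n_nodes = 10)
  fit <- optimize_laml(spec, co, LT_DEFAULT, control = CTRL_FAST)
  expect_true(fit$converged)
  # EDF between the penalty null-space dimension (4 for a 2-D tensor) and p
  expect_gte(fit$edf, 4 - 1e-6)
  expect_lte(fit$edf, spec$p)
  refit <- fit_inner(fit$lambda, prep = prep_likelihood(spec, co, LT_DEFAULT))
  expect_equal(refit$beta, fit$beta, tolerance = 1e-8)
})

test_that("curvature in the true hazard lowers the selected time smoothing", {
  mk <- function(shape, seed) {
    generate_cohort(scenario_config(
      n_subjects = 1200, seed = seed, effect_kind = "null",
      baseline_excess_hazard = list(scale = 4, shape = shape)), LT_DEFAULT)
  }
  lam_t <- function(co) {
    spec <- model_spec_from_cohort("M0", co, k = c(time = 5, age = 3, edi = 3),
                                   n_nodes = 10)
    optimize_laml(spec, co, LT_DEFAULT, control = CTRL_FAST)$lambda[1]
  }
  expect_lt(lam_t(mk(0.55, 21)), lam_t(mk(1.0, 21)))
})

test_that("corrected AIC follows its small-sample formula", {
  fake <- structure(list(loglik = -100, edf = 5, n_events = 200),
                    class = "eh_fit")
  expect_equal(corrected_aic(fake), 200 + 10 + 60 / 194)
  expect_equal(corrected_aic(fake, variant = "plain"), 210)
  expect_gt(corrected_aic(fake), corrected_aic(fake, variant = "plain"))
  tiny <- structure(list(loglik = -10, edf = 5, n_events = 6),
                    class = "eh_fit")
  expect_error(corrected_aic(tiny), "undefined")
})

test_that("fitted models survive a JSON round trip", {
  co <- prop_cohort(400, seed = 22)
  spec <- model_spec_from_cohort("M1", co, k = c(time = 4, age = 3, edi = 3),
                                 n_nodes = 10)
  fit <- optimize_laml(spec, co, LT_DEFAULT, control = CTRL_FAST)
  f <- tempfile(fileext = ".json")
  write_fit_json(fit, f)
  fit2 <- read_fit_json(f)
  expect_equal(fit2$beta, fit$beta)
  expect_equal(fit2$lambda, fit$lambda)
  expect_equal(fit2$aicc, fit$aicc)
  grid <- c(0.5, 1, 3)
  expect_equal(predict_net_survival(fit2, 70, 0, grid)$surv,
               predict_net_survival(fit, 70, 0, grid)$surv)
  unlink(f)
})
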