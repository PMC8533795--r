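test_that("knots sit at percentiles of the deceased", {
  ks <- place_knots(1:100, 5, "time")
  expect_equal(ks$values, c(1, 25.75, 50.5, 75.25, 100))
  expect_error(place_knots(1:100, 2), "at least 3")
  expect_error(place_knots(rep(4, 50), 5), "degenerate")
  expect_error(knot_set(c(1, 2, 2), "time"), "strictly increasing")
})

test_that("restricted cubic basis is linear beyond the boundary knots", {
  kn <- knot_set(c(0, 1, 2.5, 4, 7), "time")
  far <- c(-3, -1.5, 8, 12, 30)
  d2 <- rcs_basis(far, kn, deriv = 2)$design
  expect_true(all(abs(d2) < 1e-12))
  # linearity check on raw values outside the knot span
  B <- rcs_basis(c(8, 10, 12), kn)$design
  expect_equal(B[3, ] - B[2, ], B[2, ] - B[1, ], tolerance = 1e-10)
})

test_that("each basis column is a genuine piecewise cubic (polynomial-piece oracle)", {
  kn <- knot_set(c(0, 1, 2.5, 4, 7), "edi")
  for (i in seq_len(4)) {
    lo <- kn$values[i]; hi <- kn$values[i + 1]
    x_fit <- seq(lo, hi, length.out = 4)
    x_chk <- lo + (hi - lo) * c(0.21, 0.68)
    Bf <- rcs_basis(x_fit, kn)$design
    Bc <- rcs_basis(x_chk, kn)$design
    for (j in seq_len(ncol(Bf))) {
      cf <- solve(outer(x_fit, 0:3, `^`), Bf[, j])   # exact cubic through 4 pts
      expect_equal(drop(outer(x_chk, 0:3, `^`) %*% cf), Bc[, j],
                   tolerance = 1e-8)
    }
  }
})

test_that("linear functions lie in the curvature-penalty null space", {
  kn <- knot_set(c(-2, 0, 1, 3, 6), "edi")
  bb <- rcs_basis(seq(-2, 6, by = 0.5), kn)
  S <- bb$penalties[[1]]
  # column 1 of the block is the (centred, scaled) identity function
  beta_lin <- c(3.7, rep(0, ncol(S) - 1))
  expect_lt(drop(beta_lin %*% S %*% beta_lin), 1e-12)
  # and the basis reproduces linear functions exactly within the knot span
  x <- seq(-2, 6, length.out = 41)
  B <- rcs_basis(x, kn)$design
  fit <- lm.fit(cbind(1, B), 2 - 0.5 * x)
  expect_lt(max(abs(fit$residuals)), 1e-10)
})

test_that("penalty quadratic form equals numerical integration of squared curvature", {
  set.seed(42)
  kn <- knot_set(sort(runif(6, 0, 10)), "time")
  bb <- rcs_basis(1, kn)
  S <- bb$penalties[[1]]
  for (r in 1:5) {
    beta <- rnorm(ncol(S))
    xg <- seq(kn$values[1], kn$values[length(kn$values)], length.out = 20001)
    d2 <- rcs_basis(xg, kn, deriv = 2)$design %*% beta
    num <- sum((d2[-1]^2 + d2[-length(d2)]^2) / 2) * diff(xg)[1]
    expect_equal(drop(beta %*% S %*% beta), num, tolerance = 1e-6)
  }
})

test_that("tensor bases have Kronecker dimensions and penalties", {
  set.seed(7)
  x <- runif(50); y <- runif(50)
  b1 <- rcs_basis(x, knot_set(c(0, .2, .4, .6, .8, 1), "time"))  # 5 cols
  b2 <- rcs_basis(y, knot_set(c(0, .3, .6, .9, 1.2), "age"))     # 4 cols
  tb <- tensor_basis(list(b1, b2))
  expect_equal(ncol(tb$design), 20)
  expect_length(tb$penalties, 2)
  expect_true(all(vapply(tb$penalties, function(S) all(dim(S) == 20),
                         logical(1))))
  # identity margin: tensor collapses to the other margin
  ones <- basis_block(matrix(1, 50, 1), list(matrix(0, 1, 1)), "const")
  expect_equal(tensor_basis(list(b1, ones))$design, b1$design,
               ignore_attr = TRUE)
  expect_error(tensor_basis(list(b1)), "2 or 3")
})

test_that("tensor penalty quadratic form matches a quadrature oracle", {
  # beta' (S_t x I) beta must equal the summed time-roughness of the
  # age-coefficient functions f_k(t); check against dense quadrature
  set.seed(8)
  knt <- knot_set(c(0, 1, 2, 4, 5.5), "time")
  kna <- knot_set(c(50, 60, 70, 85), "age")
  bt <- rcs_basis(0.5, knt); ba <- rcs_basis(55, kna)
  tb <- tensor_basis(list(rcs_basis(runif(10, 0, 5.5), knt),
                          rcs_basis(runif(10, 50, 85), kna)))
  S_time <- tb$penalties[[1]]
  p_t <- 4; p_a <- 3
  beta <- rnorm(p_t * p_a)
  qf <- drop(beta %*% S_time %*% beta)
  xg <- seq(0, 5.5, length.out = 20001)
  D2 <- rcs_basis(xg, knt, deriv = 2)$design
  B <- matrix(beta, p_t, p_a)              # time index fastest
  num <- 0
  for (k in seq_len(p_a)) {
    d2 <- D2 %*% B[, k]
    num <- num + sum((d2[-1]^2 + d2[-length(d2)]^2) / 2) * diff(xg)[1]
  }
  expect_equal(qf, num, tolerance = 1e-6)
})

test_that("interaction-only tensors carry no marginal main effects", {
  knt <- knot_set(c(0, 1, 3, 5), "time")
  kne <- knot_set(c(-5, -1, 2, 6), "edi")
  # columns average to zero over the marginal reference grids
  eg <- seq(-5, 6, length.out = 201)
  tb <- interaction_tensor_basis(list(
    rcs_basis(rep(2.2, length(eg)), knt), rcs_basis(eg, kne)))
  expect_lt(max(abs(colMeans(tb$design))), 1e-10)
  expect_equal(ncol(tb$design), 3 * 3)
  expect_length(tb$penalties, 2)
  # no function of time alone is well-approximated by the block
  tg <- seq(0, 5, length.out = 41)
  grid <- expand.grid(t = tg, e = seq(-5, 6, length.out = 41))
  X <- interaction_tensor_basis(list(rcs_basis(grid$t, knt),
                                     rcs_basis(grid$e, kne)))$design
  expect_equal(qr(X)$rank, ncol(X))
  f_t <- grid$t - mean(grid$t)
  res <- lm.fit(X, f_t)$residuals
  expect_gt(sqrt(sum(res^2)) / sqrt(sum(f_t^2)), 0.5)
  expect_error(interaction_tensor_basis(list(rcs_basis(grid$t, knt))),
               "exactly 2")
})

test_that("all model penalties are symmetric positive semi-definite", {
  co <- prop_cohort(400, seed = 5)
  for (st in c("M0", "M1", "M1b", "M2")) {
    spec <- model_spec_from_cohort(st, co, k = c(time = 4, age = 4, edi = 4))
    for (S in model_penalties(spec)) {
      expect_equal(S, t(S))
      ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
    }
  }
})
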