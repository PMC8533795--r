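## Penalized full-likelihood estimation of the excess hazard.
##
## Log-likelihood (background cumulative hazard omitted: it is free of
## parameters):
##   l(beta) = sum_i [ d_i * log(hE(t_i) + hP_i) - LambdaE_i ]
## with hE = exp(X beta), hP the known life-table hazard at the event time,
## and LambdaE_i the Gauss-Legendre cumulative excess hazard. Penalized:
##   lp(beta) = l(beta) - 1/2 * sum_j lambda_j beta' S_j beta.
## Regression coefficients by Newton-Raphson with step halving; smoothing
## parameters by maximizing the Laplace approximate marginal likelihood
## (LAML); structures compared by corrected AIC on the unpenalized
## log-likelihood with effective degrees of freedom.

#' Precompute likelihood ingredients for a (spec, cohort, life table) triple
#'
#' Builds the event-row design, the event-time background hazards and the
#' stacked quadrature design once, so repeated likelihood evaluations during
#' Newton and LAML iterations are pure linear algebra.
#'
#' @param spec a [model_spec()]
#' @param cohort an `eh_cohort`
#' @param lt a [lifetable()]
#' @return list used by [penalized_log_likelihood()] and [fit_inner()]
#' @export
prep_likelihood <- function(spec, cohort, lt) {
  ev <- cohort$event == 1
  edi <- if (spec$structure %in% c("constant", "M0")) NULL else cohort$edi
  X_ev <- model_matrix(spec, cohort$time_years[ev], cohort$age[ev],
                       if (!is.null(edi)) edi[ev])
  hP_ev <- expected_hazard_along_followup(cohort[ev, , drop = FALSE], lt,
                                          cohort$time_years[ev])
  gl <- gauss_legendre(spec$n_nodes)
  t <- cohort$time_years
  n <- length(t)
  u <- as.vector(outer(gl$nodes + 1, t / 2))
  w <- as.vector(outer(gl$weights, t / 2))
  X_q <- model_matrix(spec, u, rep(cohort$age, each = spec$n_nodes),
                      if (!is.null(edi)) rep(edi, each = spec$n_nodes))
  blocks <- model_penalty_blocks(spec)
  ## fixed penalized-subspace rank per block (computed once, at lambda = 1)
  k <- 0
  for (b in seq_along(blocks)) {
    S1 <- Reduce(`+`, blocks[[b]]$parts)
    evals <- eigen(S1, symmetric = TRUE, only.values = TRUE)$values
    blocks[[b]]$rank <- sum(evals > max(evals) * 1e-8)
    blocks[[b]]$lambda_idx <- k + seq_along(blocks[[b]]$parts)
    k <- k + length(blocks[[b]]$parts)
  }
  list(X_ev = X_ev, hP_ev = hP_ev, X_q = X_q, w_q = w,
       n_events = sum(ev), total_time = sum(t),
       penalties = model_penalties(spec), blocks = blocks, p = spec$p)
}

.sum_penalty <- function(penalties, lambda) {
  p <- if (length(penalties)) nrow(penalties[[1]]) else 1
  S <- matrix(0, p, p)
  for (j in seq_along(penalties)) S <- S + lambda[j] * penalties[[j]]
  S
}

#' Penalized log-likelihood with analytic gradient and Hessian
#'
#' @param beta coefficients
#' @param lambda smoothing parameters, one per penalty of the model
#'   specification
#' @param spec,cohort,lt model, data and background mortality; ignored when
#'   `prep` is supplied
#' @param prep optional precomputation from [prep_likelihood()]
#' @return list with `value`, `gradient`, `hessian` (of the penalized
#'   log-likelihood), `loglik` (unpenalized), and `hessian_loglik`
#' @export
penalized_log_likelihood <- function(beta, lambda, spec = NULL, cohort = NULL,
                                     lt = NULL, prep = NULL) {
  if (is.null(prep)) prep <- prep_likelihood(spec, cohort, lt)
  if (length(lambda) != length(prep$penalties)) {
    stop("lambda must have one entry per penalty (", length(prep$penalties), ")")
  }
  S <- .sum_penalty(prep$penalties, lambda)
  eta_ev <- drop(prep$X_ev %*% beta)
  hE_ev <- exp(eta_ev)
  htot <- hE_ev + prep$hP_ev
  if (any(htot <= 0) || any(!is.finite(htot))) {
    return(list(value = -Inf, gradient = rep(NA_real_, length(beta)),
                hessian = NULL, loglik = -Inf, hessian_loglik = NULL))
  }
  eta_q <- drop(prep$X_q %*% beta)
  whE_q <- prep$w_q * exp(eta_q)
  if (any(!is.finite(whE_q))) {
    return(list(value = -Inf, gradient = rep(NA_real_, length(beta)),
                hessian = NULL, loglik = -Inf, hessian_loglik = NULL))
  }
  ll <- sum(log(htot)) - sum(whE_q)
  Sb <- drop(S %*% beta)
  value <- ll - 0.5 * sum(beta * Sb)

  r_ev <- hE_ev / htot
  grad_ll <- drop(crossprod(prep$X_ev, r_ev)) - drop(crossprod(prep$X_q, whE_q))
  gradient <- grad_ll - Sb

  c_ev <- hE_ev * prep$hP_ev / htot^2
  H_ll <- crossprod(prep$X_ev * sqrt(c_ev)) -
    crossprod(prep$X_q * sqrt(whE_q))
  list(value = value, gradient = gradient, hessian = H_ll - S,
       loglik = ll, hessian_loglik = H_ll)
}

#' Inner Newton-Raphson fit of the coefficients at fixed smoothing
#'
#' Newton steps with step halving on the penalized log-likelihood, ridge
#' stabilization when the penalized curvature is not positive definite.
#' Convergence: gradient max-norm < 1e-6 and relative penalized-likelihood
#' change < 1e-9. Non-convergence is flagged, not an exception.
#'
#' @inheritParams penalized_log_likelihood
#' @param beta_init starting coefficients; default zeros with the intercept
#'   at `log(d / T)` (events over total follow-up time)
#' @param max_iter Newton iteration cap
#' @return list(beta, converged, iterations, grad_norm, pll, loglik,
#'   hessian_pll, hessian_loglik)
#' @export
fit_inner <- function(lambda, spec = NULL, cohort = NULL, lt = NULL,
                      beta_init = NULL, prep = NULL, max_iter = 50) {
  if (is.null(prep)) prep <- prep_likelihood(spec, cohort, lt)
  p <- prep$p
  if (is.null(beta_init)) {
    beta_init <- rep(0, p)
    beta_init[1] <- log(max(prep$n_events, 1) / prep$total_time)
  }
  beta <- beta_init
  cur <- penalized_log_likelihood(beta, lambda, prep = prep)
  if (!is.finite(cur$value)) {
    beta <- rep(0, p)
    beta[1] <- log(max(prep$n_events, 1) / prep$total_time)
    cur <- penalized_log_likelihood(beta, lambda, prep = prep)
  }
  converged <- FALSE
  iter <- 0
  for (it in seq_len(max_iter)) {
    iter <- it
    Hp <- -cur$hessian                       # negative penalized Hessian
    ch <- tryCatch(chol(Hp), error = function(e) NULL)
    if (is.null(ch)) {
      ridge <- 1e-6 * max(abs(diag(Hp)), 1)
      repeat {
        ch <- tryCatch(chol(Hp + ridge * diag(p)), error = function(e) NULL)
        if (!is.null(ch)) break
        ridge <- ridge * 10
        if (ridge > 1e8) stop("penalized Hessian could not be stabilized")
      }
    }
    step <- backsolve(ch, forwardsolve(t(ch), cur$gradient))
    ## step halving
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      nxt <- penalized_log_likelihood(cand, lambda, prep = prep)
      if (is.finite(nxt$value) && nxt$value >= cur$value - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 2^-30) break
    }
    if (alpha < 2^-30) break
    rel_change <- abs(nxt$value - cur$value) / (abs(cur$value) + 1e-10)
    beta <- cand
    cur <- nxt
    if (max(abs(cur$gradient)) < 1e-6 && rel_change < 1e-9) {
      converged <- TRUE
      break
    }
  }
  list(beta = beta, converged = converged, iterations = iter,
       grad_norm = max(abs(cur$gradient)), pll = cur$value,
       loglik = cur$loglik, hessian_pll = cur$hessian,
       hessian_loglik = cur$hessian_loglik)
}

## generalized log-determinant of S_lambda over the penalized subspace,
## block-wise with the fixed rank per block; null-space dimension counts
## all unpenalized directions (including the intercept/tensor null space)
.logdet_plus <- function(blocks, lambda, p) {
  logdet <- 0
  rank_total <- 0
  for (b in blocks) {
    Sb <- matrix(0, length(b$cols), length(b$cols))
    for (j in seq_along(b$parts)) {
      Sb <- Sb + lambda[b$lambda_idx[j]] * b$parts[[j]]
    }
    ev <- sort(eigen(Sb, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)[seq_len(b$rank)]
    ev <- pmax(ev, max(ev) * 1e-15)         # guard eigen round-off
    logdet <- logdet + sum(log(ev))
    rank_total <- rank_total + b$rank
  }
  list(logdet = logdet, rank = rank_total, null_dim = p - rank_total)
}

#' Laplace approximate marginal likelihood at fixed smoothing parameters
#'
#' LAML = lp(beta_hat) + 1/2 log|S_lambda|_+ - 1/2 log|Hp(beta_hat)| +
#' (Mp/2) log(2 pi), with |.|_+ the generalized determinant over the
#' penalized subspace, Hp the negative penalized Hessian and Mp the penalty
#' null-space dimension. Larger is better.
#'
#' @inheritParams fit_inner
#' @return list(laml, fit, logdet_S, logdet_Hp, null_dim)
#' @export
laml <- function(lambda, spec = NULL, cohort = NULL, lt = NULL,
                 beta_init = NULL, prep = NULL) {
  if (is.null(prep)) prep <- prep_likelihood(spec, cohort, lt)
  fit <- fit_inner(lambda, beta_init = beta_init, prep = prep)
  Sld <- .logdet_plus(prep$blocks, lambda, prep$p)
  Hp <- -fit$hessian_pll
  ch <- tryCatch(chol(Hp), error = function(e) NULL)
  if (is.null(ch)) {
    ridge <- 1e-7 * max(abs(diag(Hp)), 1)
    ch <- tryCatch(chol(Hp + ridge * diag(nrow(Hp))), error = function(e) NULL)
    if (is.null(ch)) stop("indefinite penalized Hessian in LAML")
  }
  logdet_Hp <- 2 * sum(log(diag(ch)))
  val <- fit$pll + 0.5 * Sld$logdet - 0.5 * logdet_Hp +
    0.5 * Sld$null_dim * log(2 * pi)
  list(laml = val, fit = fit, logdet_S = Sld$logdet,
       logdet_Hp = logdet_Hp, null_dim = Sld$null_dim)
}

#' Fit an excess-hazard model with LAML-selected smoothing
#'
#' Outer maximization of the LAML over log smoothing parameters
#' (Nelder-Mead, Brent for a single penalty), multistarted from all
#' penalties at 0.1 and all at 10, with warm-started inner Newton fits.
#'
#' @inheritParams prep_likelihood
#' @param control list: `outer_maxit` (default 100), `outer_reltol`
#'   (default 1e-7), `starts` (vector of common start values, default
#'   c(0.1, 10)), `max_iter` inner Newton cap
#' @return object of class `eh_fit`
#' @export
optimize_laml <- function(spec, cohort, lt, control = list()) {
  ctrl <- utils::modifyList(
    list(outer_maxit = 100, outer_reltol = 1e-7, starts = c(0.1, 10),
         max_iter = 50),
    control
  )
  prep <- prep_likelihood(spec, cohort, lt)
  d <- length(prep$penalties)
  warm <- new.env(parent = emptyenv())
  warm$beta <- NULL
  ## bounded search box: keeps within-block smoothing ratios resolvable in
  ## double precision and stops degenerate drift to 0 or infinity
  box <- ctrl$log_lambda_box %||% 12
  objective <- function(log_lambda) {
    ll <- pmin(pmax(log_lambda, -box), box)
    res <- tryCatch(
      laml(exp(ll), beta_init = warm$beta, prep = prep),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$laml)) return(1e10)
    warm$beta <- res$fit$beta
    -res$laml
  }
  if (d == 0) {
    lambda_hat <- numeric(0)
  } else if (d == 1) {
    opt <- stats::optimize(objective, interval = c(-box, box), tol = 1e-4)
    lambda_hat <- exp(opt$minimum)
  } else {
    best <- NULL
    for (s in ctrl$starts) {
      warm$beta <- NULL
      opt <- stats::optim(rep(log(s), d), objective, method = "Nelder-Mead",
                          control = list(maxit = ctrl$outer_maxit,
                                         reltol = ctrl$outer_reltol))
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (best$value >= 1e10) stop("all LAML starts failed")
    lambda_hat <- exp(pmin(pmax(best$par, -box), box))
  }
  final <- laml(lambda_hat, prep = prep)
  fit <- final$fit
  Hp <- -fit$hessian_pll
  Vp <- tryCatch(chol2inv(chol(Hp)), error = function(e) {
    chol2inv(chol(Hp + 1e-7 * max(abs(diag(Hp))) * diag(nrow(Hp))))
  })
  H_unpen <- -fit$hessian_loglik
  edf <- sum(Vp * H_unpen)                 # trace(Vp %*% H_unpen), symmetric
  out <- list(
    spec = spec, beta = fit$beta, lambda = lambda_hat,
    lambda_names = names(prep$penalties),
    Vp = Vp, edf = edf, loglik = fit$loglik, pll = fit$pll,
    laml = final$laml, n_events = prep$n_events,
    total_time = prep$total_time,
    converged = fit$converged, iterations = fit$iterations,
    grad_norm = fit$grad_norm
  )
  class(out) <- "eh_fit"
  out$aic <- corrected_aic(out, variant = "plain")
  out$aicc <- tryCatch(corrected_aic(out, variant = "aicc"),
                       error = function(e) NA_real_)
  out
}

#' @export
print.eh_fit <- function(x, ...) {
  cat("Excess-hazard fit:", x$spec$structure,
      "|", length(x$beta), "coefficients, EDF", format(round(x$edf, 2)), "\n")
  cat("  log-likelihood", format(round(x$loglik, 3)),
      "| AICc", format(round(x$aicc, 3)),
      "| events", x$n_events, "\n")
  if (length(x$lambda)) {
    cat("  lambda:", paste(sprintf("%s=%.3g", x$lambda_names, x$lambda),
                           collapse = ", "), "\n")
  }
  if (!x$converged) cat("  WARNING: inner Newton did not converge\n")
  invisible(x)
}

#' Corrected Akaike information criterion
#'
#' `AICc = -2 l + 2 EDF + 2 EDF (EDF + 1) / (n_events - EDF - 1)` with `l`
#' the unpenalized log-likelihood at the penalized estimate and the event
#' count as the effective sample size; `variant = "plain"` gives
#' `-2 l + 2 EDF`.
#'
#' @param fit an `eh_fit`
#' @param variant "aicc" (default) or "plain"
#' @export
corrected_aic <- function(fit, variant = c("aicc", "plain")) {
  variant <- match.arg(variant)
  base <- -2 * fit$loglik + 2 * fit$edf
  if (variant == "plain") return(base)
  denom <- fit$n_events - fit$edf - 1
  if (denom <= 0) stop("AICc undefined: events <= EDF + 1")
  base + 2 * fit$edf * (fit$edf + 1) / denom
}

#' Serialize / reload a fitted model as JSON
#'
#' Stores structure, knots, quadrature order, coefficients, smoothing
#' parameters, posterior covariance and criteria, allowing exact reload.
#'
#' @param fit an `eh_fit`
#' @param path file path
#' @export
write_fit_json <- function(fit, path) {
  x <- list(
    structure = fit$spec$structure,
    n_nodes = fit$spec$n_nodes,
    tint_two_lambdas = fit$spec$tint_two_lambdas,
    knots = lapply(fit$spec$knots, function(k) k$values),
    beta = fit$beta, lambda = fit$lambda, lambda_names = fit$lambda_names,
    Vp = fit$Vp, edf = fit$edf, loglik = fit$loglik, pll = fit$pll,
    laml = fit$laml, aic = fit$aic, aicc = fit$aicc,
    n_events = fit$n_events, total_time = fit$total_time,
    converged = fit$converged, iterations = fit$iterations,
    grad_norm = fit$grad_norm
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  knots <- lapply(names(x$knots), function(nm) knot_set(x$knots[[nm]], nm))
  names(knots) <- names(x$knots)
  spec <- model_spec(x$structure, knots, x$n_nodes, x$tint_two_lambdas)
  out <- list(
    spec = spec, beta = as.numeric(x$beta), lambda = as.numeric(x$lambda),
    lambda_names = x$lambda_names,
    Vp = matrix(unlist(x$Vp), spec$p, spec$p),
    edf = x$edf, loglik = x$loglik, pll = x$pll, laml = x$laml,
    aic = x$aic, aicc = x$aicc, n_events = x$n_events,
    total_time = x$total_time, converged = x$converged,
    iterations = x$iterations, grad_norm = x$grad_norm
  )
  class(out) <- "eh_fit"
  out
}
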