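## Predictions from a fitted excess-hazard model: net survival curves and
## excess hazard ratios at the deprivation quintile medians, with Wald
## 95% intervals from the posterior covariance (delta method; net survival
## on the log-cumulative-hazard scale).

#' Median EDI of the national deprivation quintiles
#'
#' Default values are the national quintile medians used as evaluation
#' points throughout: mQ1 (least deprived) = -4.2, mQ2 = -2.4, mQ3 = -0.9,
#' mQ4 = 0.8, mQ5 (most deprived) = 5.1.
#'
#' @param values 5 strictly increasing EDI values
#' @export
quintile_medians <- function(values = c(-4.2, -2.4, -0.9, 0.8, 5.1)) {
  values <- as.numeric(values)
  if (length(values) != 5 || is.unsorted(values, strictly = TRUE)) {
    stop("quintile medians must be 5 strictly increasing EDI values")
  }
  names(values) <- paste0("mQ", 1:5)
  values
}

#' Predict net survival at a covariate profile
#'
#' `S_N(t) = exp(-integral of hE(u, age, edi) du)` by Gauss-Legendre
#' quadrature; the 95% interval is Wald on the log-cumulative-hazard scale
#' using the posterior covariance of the coefficients.
#'
#' @param fit an `eh_fit`
#' @param age age at diagnosis (years), default 70
#' @param edi deprivation score at which to predict
#' @param time_grid evaluation times (years since diagnosis)
#' @param n_nodes quadrature nodes (defaults to the fit's)
#' @return data.frame of class `net_survival_curve`: time, surv, lo, hi
#' @export
predict_net_survival <- function(fit, age = 70, edi = NULL, time_grid,
                                 n_nodes = NULL) {
  spec <- fit$spec
  n_nodes <- n_nodes %||% spec$n_nodes
  gl <- gauss_legendre(n_nodes)
  G <- length(time_grid)
  surv <- lo <- hi <- numeric(G)
  last_knot <- if (spec$structure == "constant") Inf else
    max(spec$knots$time$values)
  if (any(time_grid > last_knot)) {
    warning("prediction beyond the last time knot: linear-tail behaviour applies")
  }
  for (g in seq_len(G)) {
    tt <- time_grid[g]
    if (tt == 0) {
      surv[g] <- 1; lo[g] <- 1; hi[g] <- 1
      next
    }
    u <- tt / 2 * (gl$nodes + 1)
    w <- tt / 2 * gl$weights
    X <- model_matrix(spec, u, rep(age, n_nodes),
                      if (!is.null(edi)) rep(edi, n_nodes))
    hE <- exp(drop(X %*% fit$beta))
    Lam <- sum(w * hE)
    gvec <- drop(crossprod(X, w * hE))
    se_log <- sqrt(max(drop(gvec %*% fit$Vp %*% gvec), 0)) / Lam
    surv[g] <- exp(-Lam)
    lo[g] <- exp(-Lam * exp(z95 * se_log))
    hi[g] <- exp(-Lam * exp(-z95 * se_log))
  }
  out <- data.frame(time = time_grid, surv = surv, lo = lo, hi = hi)
  attr(out, "age") <- age
  attr(out, "edi") <- edi
  attr(out, "type") <- "model"
  class(out) <- c("net_survival_curve", "data.frame")
  out
}

#' Excess hazard ratios versus the least deprived quintile median
#'
#' EHR(t) = hE(t, age, mQk) / hE(t, age, mQ1), with Wald 95% intervals on
#' the log scale from the posterior covariance. For structures with a
#' time-constant EDI effect (M1) a single row per quintile is reported
#' (`time = NA`); for time-dependent structures (M1b, M2) the default
#' report times are 1 month, 1 year and 5 years.
#'
#' @param fit an `eh_fit`
#' @param age reference age (default 70)
#' @param times follow-up times; `NULL` picks the structure's default
#' @param medians [quintile_medians()]
#' @return data.frame of class `ehr_table`: time, quintile, edi, ehr, lo, hi
#' @export
compute_ehr <- function(fit, age = 70, times = NULL,
                        medians = quintile_medians()) {
  spec <- fit$spec
  if (is.null(times)) {
    times <- if (spec$structure %in% c("M1b", "M2")) c(1 / 12, 1, 5) else NA_real_
  }
  if (spec$structure %in% c("constant", "M0", "M1") && length(times) > 1) {
    times <- times[1]   # effect time-constant: one row per quintile
  }
  rows <- list()
  for (tt in times) {
    t_eval <- if (is.na(tt)) 1 else tt
    X <- model_matrix(spec, rep(t_eval, 5), rep(age, 5),
                      if (!spec$structure %in% c("constant", "M0")) medians)
    D <- sweep(X, 2, X[1, ], `-`)            # contrasts vs mQ1
    log_ehr <- drop(D %*% fit$beta)
    se <- sqrt(pmax(rowSums((D %*% fit$Vp) * D), 0))
    rows[[length(rows) + 1]] <- data.frame(
      time = tt, quintile = 1:5, edi = unname(medians),
      ehr = exp(log_ehr),
      lo = exp(log_ehr - z95 * se),
      hi = exp(log_ehr + z95 * se)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "age") <- age
  class(out) <- c("ehr_table", "data.frame")
  out
}

#' Population-averaged model net survival
#'
#' Mean over the cohort of each subject's predicted net survival (the
#' model-based analogue of a marginal, Pohar-Perme-style curve).
#'
#' @param fit an `eh_fit`
#' @param cohort an `eh_cohort`
#' @param times evaluation times
#' @param n_nodes quadrature nodes per time point
#' @export
population_net_survival <- function(fit, cohort, times, n_nodes = NULL) {
  spec <- fit$spec
  n_nodes <- n_nodes %||% spec$n_nodes
  gl <- gauss_legendre(n_nodes)
  n <- nrow(cohort)
  use_edi <- !spec$structure %in% c("constant", "M0")
  out <- numeric(length(times))
  chunk <- 1000L
  for (s in seq(1, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    m <- length(idx)
    Smat <- matrix(0, m, length(times))
    for (g in seq_along(times)) {
      tt <- times[g]
      if (tt == 0) { Smat[, g] <- 1; next }
      u <- rep(tt / 2 * (gl$nodes + 1), m)
      X <- model_matrix(spec, u, rep(cohort$age[idx], each = n_nodes),
                        if (use_edi) rep(cohort$edi[idx], each = n_nodes))
      hE <- matrix(exp(drop(X %*% fit$beta)), n_nodes, m)
      Smat[, g] <- exp(-colSums(tt / 2 * gl$weights * hE))
    }
    out <- out + colSums(Smat)
  }
  out / n
}
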