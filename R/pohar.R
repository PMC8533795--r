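## Pohar-Perme non-parametric net survival estimator.
##
## Counting processes are weighted by each subject's inverse expected
## survival 1/S_Pi(t). Observed deaths enter through the weighted
## product-limit; the population hazard is removed through the integrated
## weighted population term:
##   S_N(t) = prod_{s <= t} (1 - dN^w(s) / Y^w(s)) *
##            exp(+ int_0^t [sum_i Y_i(u) hP_i(u)/S_Pi(u)] /
##                          [sum_i Y_i(u)/S_Pi(u)] du).
## With hP = 0 all weights are 1 and the estimator reduces exactly to
## Kaplan-Meier.

#' Pohar-Perme net survival estimator
#'
#' @param cohort an `eh_cohort` (columns time_years, event, age, diag_date,
#'   sex, region, and edi_q if `lt` is quintile-stratified)
#' @param lt a [lifetable()] supplying the expected mortality of each subject
#' @param time_grid times at which to report the curve; defaults to a grid to
#'   the last observed time
#' @param int_step maximum sub-interval (years) for the population-hazard
#'   integral between consecutive observed times
#' @return data.frame of class `net_survival_curve` (type "pohar-perme"):
#'   time, surv, lo, hi
#' @export
pohar_perme <- function(cohort, lt, time_grid = NULL, int_step = 1 / 24) {
  if (nrow(cohort) == 0) stop("empty cohort")
  tmax_obs <- max(cohort$time_years)
  if (is.null(time_grid)) {
    time_grid <- seq(0, tmax_obs, length.out = 101)
  }
  tmax <- min(max(time_grid), tmax_obs)

  obs_times <- sort(unique(cohort$time_years[cohort$time_years <= tmax]))
  brk <- sort(unique(c(0, obs_times, tmax,
                       seq(0, tmax, by = int_step))))
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  widths <- diff(brk)
  M <- length(mids)

  ## per-subject accumulation of weighted risk sets and the population term
  num <- numeric(M)    # sum_i Y_i(m) hP_i(m) / S_Pi(m)
  den <- numeric(M)    # sum_i Y_i(m) / S_Pi(m)
  death_times <- sort(unique(cohort$time_years[cohort$event == 1 &
                                                 cohort$time_years <= tmax]))
  dNw <- numeric(length(death_times))
  Yw <- numeric(length(death_times))

  dy <- decimal_year(cohort$diag_date)
  has_q <- !is.null(lt$quintiles)
  for (i in seq_len(nrow(cohort))) {
    ti <- cohort$time_years[i]
    at_risk_m <- which(mids <= ti)           # risk sets change only at brk
    at_risk_d <- which(death_times <= ti)
    if (!length(at_risk_m) && !length(at_risk_d)) next
    eval_t <- c(mids[at_risk_m], death_times[at_risk_d])
    rec <- cohort[i, , drop = FALSE]
    cum <- drop(expected_cumhaz(rec, lt, eval_t))
    hP <- lookup_expected_hazard(
      lt, rec$age + eval_t, dy[i] + eval_t,
      rep(rec$sex, length(eval_t)), rep(rec$region, length(eval_t)),
      if (has_q) rep(rec$edi_q, length(eval_t)) else NULL
    )
    wgt <- exp(cum)                          # 1 / S_Pi
    km <- length(at_risk_m)
    if (km) {
      num[at_risk_m] <- num[at_risk_m] + hP[seq_len(km)] * wgt[seq_len(km)]
      den[at_risk_m] <- den[at_risk_m] + wgt[seq_len(km)]
    }
    if (length(at_risk_d)) {
      wd <- wgt[km + seq_along(at_risk_d)]
      Yw[at_risk_d] <- Yw[at_risk_d] + wd
      if (cohort$event[i] == 1) {
        j <- match(ti, death_times)
        dNw[j] <- dNw[j] + wd[length(wd)]
      }
    }
  }

  ## truncate where the weighted at-risk set vanishes
  ok_d <- Yw > 0
  if (any(!ok_d)) {
    warning("weighted at-risk set exhausted before the last requested time; ",
            "curve truncated")
  }
  jump_factor <- ifelse(ok_d, 1 - dNw / pmax(Yw, .Machine$double.eps), NA)
  pop_rate <- ifelse(den > 0, num / den, 0)
  cum_pop <- c(0, cumsum(pop_rate * widths))   # at brk

  surv_at <- function(tt) {
    jumps <- death_times <= tt & ok_d
    if (any(death_times <= tt & !ok_d)) return(NA_real_)
    pl <- prod(jump_factor[jumps])
    k <- findInterval(tt, brk, rightmost.closed = TRUE)
    pop <- cum_pop[k] + if (k <= length(pop_rate))
      pop_rate[k] * (tt - brk[k]) else 0
    pl * exp(pop)
  }
  surv <- vapply(pmin(time_grid, tmax), surv_at, numeric(1))
  if (any(time_grid > tmax_obs)) {
    warning("no subjects under observation beyond ",
            signif(tmax_obs, 4), " years; curve truncated")
    surv[time_grid > tmax_obs] <- NA_real_
  }

  ## variance of the cumulative weighted excess hazard (sum of squared
  ## weighted increments), delta method for the curve
  var_inc <- cumsum(dNw / pmax(Yw, .Machine$double.eps)^2)
  se_at <- function(tt) {
    jumps <- which(death_times <= tt)
    if (!length(jumps)) return(0)
    sqrt(var_inc[max(jumps)])
  }
  seL <- vapply(pmin(time_grid, tmax), se_at, numeric(1))
  out <- data.frame(
    time = time_grid, surv = surv,
    lo = pmax(surv * exp(-z95 * seL), 0),
    hi = pmin(surv * exp(z95 * seL), 1)
  )
  attr(out, "type") <- "pohar-perme"
  class(out) <- c("net_survival_curve", "data.frame")
  out
}
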