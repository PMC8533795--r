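## Expected (background) mortality life tables.
##
## Rates are all-cause hazards per person-year, piecewise constant on
## 1-year age x 1-year calendar period cells (Lexis squares), indexed by
## sex and region and optionally by deprivation quintile.

#' Construct a life table from a long-format table of rates
#'
#' @param data data.frame with columns `age` (integer years), `year`
#'   (calendar year), `sex`, `region`, optional `quintile` (1..5), and
#'   `rate` (hazard per person-year, >= 0). The table must be dense: every
#'   combination of the declared ranges must appear exactly once, and the
#'   quintile dimension, when present, must be complete (all of 1..5).
#' @return object of class `lifetable`
#' @export
lifetable <- function(data) {
  req <- c("age", "year", "sex", "region", "rate")
  if (!all(req %in% names(data))) {
    stop("life table needs columns: ", paste(req, collapse = ", "))
  }
  has_q <- "quintile" %in% names(data)
  ages <- sort(unique(as.integer(data$age)))
  years <- sort(unique(as.integer(data$year)))
  sexes <- sort(unique(as.character(data$sex)))
  regions <- sort(unique(as.character(data$region)))
  quintiles <- if (has_q) sort(unique(as.integer(data$quintile))) else NULL
  if (has_q && !identical(quintiles, 1:5)) {
    stop("quintile dimension must be complete (1..5) or absent")
  }
  if (!identical(ages, min(ages):max(ages)) ||
      !identical(years, min(years):max(years))) {
    stop("age and year ranges must be contiguous 1-year bands")
  }
  if (any(data$rate < 0) || any(!is.finite(data$rate))) {
    stop("all rates must be finite and >= 0")
  }
  dims <- c(length(ages), length(years), length(sexes), length(regions),
            if (has_q) 5L)
  n_expected <- prod(dims)
  if (nrow(data) != n_expected) {
    stop(sprintf("life table not dense: %d rows, %d cells expected",
                 nrow(data), n_expected))
  }
  idx <- cbind(match(as.integer(data$age), ages),
               match(as.integer(data$year), years),
               match(as.character(data$sex), sexes),
               match(as.character(data$region), regions))
  if (has_q) idx <- cbind(idx, match(as.integer(data$quintile), 1:5))
  if (anyNA(idx)) stop("life table contains unmatchable cells")
  if (anyDuplicated(idx)) stop("life table contains duplicated cells")
  rates <- array(NA_real_, dims)
  rates[idx] <- data$rate
  if (anyNA(rates)) stop("life table not dense over declared ranges")
  structure(
    list(rates = rates, ages = ages, years = years, sexes = sexes,
         regions = regions, quintiles = quintiles),
    class = "lifetable"
  )
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Life table: ages", min(x$ages), "-", max(x$ages),
      ", years", min(x$years), "-", max(x$years),
      ",", length(x$sexes), "sex(es),", length(x$regions), "region(s)")
  if (!is.null(x$quintiles)) cat(", stratified by deprivation quintile")
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.lifetable <- function(x, ...) {
  g <- expand.grid(age = x$ages, year = x$years, sex = x$sexes,
                   region = x$regions,
                   quintile = if (is.null(x$quintiles)) NA else 1:5,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g$rate <- as.vector(x$rates)
  if (is.null(x$quintiles)) g$quintile <- NULL
  g
}

#' Write / read a life table as long-format CSV
#' @param lt a `lifetable`
#' @param path file path
#' @export
write_lifetable_csv <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lifetable_csv
#' @export
read_lifetable_csv <- function(path) {
  lifetable(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Synthetic national life table with Gompertz age structure
#'
#' A stand-in for national all-cause mortality tables: hazard
#' `A * exp(B * age)` with a female advantage and a mild secular decline,
#' calibrated so that rates at ages 40/70/90 are of the order seen in
#' recent Western European tables.
#'
#' @param ages integer age bands (default 0:110)
#' @param years calendar years covered
#' @param sexes,regions strata labels
#' @param A,B Gompertz level and log-slope (per year of age)
#' @param female_factor multiplicative female rate ratio
#' @param annual_decline multiplicative factor per calendar year
#' @return a `lifetable`
#' @export
synthetic_lifetable <- function(ages = 0:110, years = 2004:2016,
                                sexes = c("female", "male"),
                                regions = "R1",
                                A = 3.7e-5, B = 0.09,
                                female_factor = 0.55,
                                annual_decline = 0.99) {
  g <- expand.grid(age = ages, year = years, sex = sexes, region = regions,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- A * exp(B * g$age) * annual_decline^(g$year - min(years))
  base <- base * ifelse(g$sex == "female", female_factor, 1)
  ## infant bump + floor so young-age rates are not vanishingly small
  g$rate <- pmin(base + 2e-4 + 3e-3 * (g$age == 0), 0.7)
  lifetable(g)
}

.lt_index <- function(lt, age, year, sex, region, quintile = NULL) {
  age <- as.vector(age)
  year <- as.vector(year)
  ia <- pmin(pmax(floor(age), min(lt$ages)), max(lt$ages)) - min(lt$ages) + 1L
  iy <- pmin(pmax(floor(year), min(lt$years)), max(lt$years)) - min(lt$years) + 1L
  is <- match(as.character(sex), lt$sexes)
  ir <- match(as.character(region), lt$regions)
  if (anyNA(is)) {
    stop_coverage("life table has no stratum for sex '%s'",
                  paste(unique(sex[is.na(is)]), collapse = ","))
  }
  if (anyNA(ir)) {
    stop_coverage("life table has no stratum for region '%s'",
                  paste(unique(region[is.na(ir)]), collapse = ","))
  }
  if (is.null(lt$quintiles)) {
    cbind(ia, iy, is, ir)
  } else {
    if (is.null(quintile)) {
      stop_coverage("life table is quintile-stratified but no quintile given")
    }
    iq <- match(as.integer(quintile), 1:5)
    if (anyNA(iq)) stop_coverage("invalid deprivation quintile")
    cbind(ia, iy, is, ir, iq)
  }
}

## fast lookup with pre-resolved sex/region/quintile integer indices;
## age/year floored and clamped; assumes contiguous age/year bands
.lt_rate_fast <- function(lt, age, year, is, ir, iq = NULL) {
  na <- length(lt$ages); ny <- length(lt$years)
  ns <- length(lt$sexes); nr <- length(lt$regions)
  ia <- pmin.int(pmax.int(as.integer(age), lt$ages[1]), lt$ages[na]) - lt$ages[1]
  iy <- pmin.int(pmax.int(as.integer(year), lt$years[1]), lt$years[ny]) -
    lt$years[1]
  lin <- 1L + ia + na * iy + (na * ny) * (is - 1L) + (na * ny * ns) * (ir - 1L)
  if (!is.null(iq)) lin <- lin + (na * ny * ns * nr) * (iq - 1L)
  lt$rates[lin]
}

#' Look up the expected mortality hazard
#'
#' Age and calendar year are floored to the 1-year cell and clamped to the
#' table edges (standard relative-survival practice, so that very old
#' patients are not discarded). Vectorized over all arguments.
#'
#' @param lt a `lifetable`
#' @param age age in years (continuous)
#' @param year calendar year (continuous or integer)
#' @param sex,region stratum labels
#' @param quintile deprivation quintile 1..5; required iff `lt` is stratified.
#'   Ignored (with no error) when the table has no quintile dimension, so the
#'   same cohort can be analysed under common and stratified tables.
#' @return hazard per person-year
#' @export
lookup_expected_hazard <- function(lt, age, year, sex, region, quintile = NULL) {
  if (is.null(lt$quintiles)) quintile <- NULL
  lt$rates[.lt_index(lt, age, year, sex, region, quintile)]
}

#' Expected hazard along follow-up for cohort records
#'
#' Returns hP(age_at_diagnosis + t, year(diagnosis + t), sex, region
#' [, quintile]) for each record; piecewise constant in t within Lexis cells.
#'
#' @param records cohort data.frame (columns `age`, `diag_date`, `sex`,
#'   `region`, and `edi_q` when `lt` is stratified)
#' @param lt a `lifetable`
#' @param t time since diagnosis in years (scalar or vector matching records)
#' @export
expected_hazard_along_followup <- function(records, lt, t) {
  dy <- decimal_year(records$diag_date)
  q <- if (!is.null(lt$quintiles)) records$edi_q else NULL
  lookup_expected_hazard(lt, records$age + t, dy + t,
                         records$sex, records$region, q)
}

#' Cumulative expected hazard over follow-up, exact for Lexis cells
#'
#' Integrates the piecewise-constant background hazard of each record from 0
#' to each requested time, splitting exactly at age-band and calendar-year
#' boundaries.
#'
#' @param records cohort data.frame
#' @param lt a `lifetable`
#' @param tgrid increasing vector of times (years since diagnosis)
#' @return matrix `nrow(records)` x `length(tgrid)` of cumulative hazards
#' @export
expected_cumhaz <- function(records, lt, tgrid) {
  n <- nrow(records)
  G <- length(tgrid)
  tmax <- max(tgrid)
  out <- matrix(0, n, G)
  dy <- decimal_year(records$diag_date)
  has_q <- !is.null(lt$quintiles)
  for (i in seq_len(n)) {
    a0 <- records$age[i]
    y0 <- dy[i]
    ## segment breakpoints: crossings of integer age and integer year
    br_age <- setdiff(ceiling(a0) - a0 + 0:ceiling(tmax + 1), 0)
    br_yr <- setdiff(ceiling(y0) - y0 + 0:ceiling(tmax + 1), 0)
    brk <- sort(unique(c(0, br_age[br_age < tmax], br_yr[br_yr < tmax], tmax)))
    mid <- (brk[-1] + brk[-length(brk)]) / 2
    rate <- lookup_expected_hazard(
      lt, a0 + mid, y0 + mid,
      rep(records$sex[i], length(mid)), rep(records$region[i], length(mid)),
      if (has_q) rep(records$edi_q[i], length(mid)) else NULL
    )
    cum_br <- c(0, cumsum(rate * diff(brk)))
    ## linear in t within segments
    seg <- findInterval(tgrid, brk, rightmost.closed = TRUE)
    out[i, ] <- cum_br[seg] + rate[pmin(seg, length(rate))] * (tgrid - brk[seg])
  }
  out
}

#' Deprivation mortality rate-ratio table
#'
#' @param ratios numeric vector of 5 multiplicative rate ratios (quintile
#'   1..5, quintile 1 = least deprived). All must be > 0.
#' @export
rate_ratio_table <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) != 5 || any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("need 5 finite positive rate ratios (quintiles 1..5)")
  }
  structure(list(ratios = ratios), class = "rate_ratio_table")
}

#' Build deprivation-specific life tables from a common table
#'
#' Applies a social gradient observed in a general population to a base
#' (unstratified) life table: `rate(q) = base_rate * ratio(q)`. With
#' `renormalize = TRUE` the five rates are rescaled so their equal-weight
#' mean equals the base rate, preserving overall mortality.
#'
#' @param lt base `lifetable` without quintile dimension
#' @param rr a [rate_ratio_table()]
#' @param renormalize preserve the equal-weight mean rate per cell
#' @return a quintile-stratified `lifetable`
#' @export
build_deprivation_lifetables <- function(lt, rr, renormalize = FALSE) {
  if (!is.null(lt$quintiles)) stop("base life table already stratified")
  if (!inherits(rr, "rate_ratio_table")) rr <- rate_ratio_table(rr)
  ratios <- rr$ratios
  if (renormalize) ratios <- ratios / mean(ratios)
  rates <- outer(as.vector(lt$rates), ratios)
  dim(rates) <- c(dim(lt$rates), 5L)
  out <- lt
  out$rates <- rates
  out$quintiles <- 1:5
  out
}
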