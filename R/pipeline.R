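## End-to-end orchestration: one call runs cohort generation (or CSV
## ingestion), complete-case filtering, structure selection, predictions,
## adequacy and optional sensitivity analysis, writing CSV tables and a
## deterministic machine-readable summary.

#' Table-1-style cohort descriptives
#'
#' @param cohort an `eh_cohort`
#' @param fit optional selected `eh_fit`; adds population-averaged model net
#'   survival at 1 month, 1 year and 5 years
#' @return list: n, n_events, median_age, quintile_share (percent, 1..5),
#'   and net_survival (when `fit` is given)
#' @export
describe_cohort <- function(cohort, fit = NULL) {
  if (nrow(cohort) == 0) stop("empty cohort")
  shares <- 100 * tabulate(cohort$edi_q, nbins = 5) / nrow(cohort)
  names(shares) <- paste0("Q", 1:5)
  out <- list(
    n = nrow(cohort),
    n_events = sum(cohort$event),
    median_age = stats::median(cohort$age),
    quintile_share = shares
  )
  if (!is.null(fit)) {
    times <- c(1 / 12, 1, 5)
    ns <- population_net_survival(fit, cohort, times)
    out$net_survival <- data.frame(time = times, surv = ns)
  }
  out
}

#' Run configuration for an end-to-end analysis
#'
#' @param mode "synthetic" (generate from `scenario`) or "csv" (read
#'   `cohort_csv`)
#' @param scenario a [scenario_config()] (synthetic mode)
#' @param cohort_csv path to a cohort CSV (csv mode)
#' @param lifetable a [lifetable()], or a path to a life-table CSV, or
#'   "synthetic" for [synthetic_lifetable()] defaults
#' @param sensitivity_ratios optional 5 rate ratios; when given, a
#'   deprivation-stratified table is built and a sensitivity re-run added
#' @param knots knot counts (time, age, edi)
#' @param n_nodes quadrature nodes
#' @param aic "aicc" or "plain"
#' @param report_times EHR report times for time-dependent structures
#' @param reference_age display age for predictions (years)
#' @param medians quintile median EDI values
#' @param seed root seed (synthetic mode re-seeds the scenario with it)
#' @param output_dir where tables, fits and the summary are written
#' @param control passed to [optimize_laml()]
#' @export
run_config <- function(mode = c("synthetic", "csv"),
                       scenario = scenario_config(),
                       cohort_csv = NULL,
                       lifetable = "synthetic",
                       sensitivity_ratios = NULL,
                       knots = c(time = 6, age = 5, edi = 5),
                       n_nodes = 20,
                       aic = "aicc",
                       report_times = c(1 / 12, 1, 5),
                       reference_age = 70,
                       medians = quintile_medians(),
                       seed = 1L,
                       output_dir = tempfile("netgradient_run_"),
                       control = list()) {
  mode <- match.arg(mode)
  if (mode == "csv" && (is.null(cohort_csv) || !file.exists(cohort_csv))) {
    stop("csv mode requires an existing cohort_csv path")
  }
  if (is.character(lifetable) && lifetable != "synthetic" &&
      !file.exists(lifetable)) {
    stop("life-table file not found: ", lifetable)
  }
  structure(list(
    mode = mode, scenario = scenario, cohort_csv = cohort_csv,
    lifetable = lifetable, sensitivity_ratios = sensitivity_ratios,
    knots = knots, n_nodes = n_nodes, aic = aic,
    report_times = report_times, reference_age = reference_age,
    medians = medians, seed = as.integer(seed), output_dir = output_dir,
    control = control
  ), class = "run_config")
}

## canonical JSON of the scientific part of a config (no paths), for hashing
.config_fingerprint <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  x$cohort_csv <- NULL
  if (inherits(x$lifetable, "lifetable")) x$lifetable <- "in-memory"
  if (inherits(x$scenario, "scenario_config")) {
    s <- unclass(x$scenario)
    s$diagnosis_window <- format(s$diagnosis_window, "%Y-%m-%d")
    s$admin_censor_date <- format(s$admin_censor_date, "%Y-%m-%d")
    x$scenario <- s
  }
  f <- tempfile()
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configuration (and its seed): generates or loads
#' the cohort, drops records with missing EDI (complete-case rule, count
#' logged), selects the model structure by corrected AIC, predicts net
#' survival and excess hazard ratios at the quintile medians and reference
#' age, checks adequacy against Pohar-Perme, optionally re-runs under a
#' deprivation-stratified life table, and writes CSV tables, serialized
#' fits and a machine-readable `summary.json` into the output directory.
#'
#' @param config a [run_config()]
#' @param quiet suppress progress messages
#' @return invisibly, the summary list (also written as JSON)
#' @export
run_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(...)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  fingerprint <- .config_fingerprint(config)

  lt <- config$lifetable
  if (is.character(lt)) {
    lt <- if (lt == "synthetic") synthetic_lifetable() else read_lifetable_csv(lt)
  }

  if (config$mode == "synthetic") {
    scenario <- config$scenario
    scenario$seed <- config$seed
    say("generating synthetic cohort (n = ", scenario$n_subjects, ")")
    cohort <- generate_cohort(scenario, lt)
  } else {
    say("reading cohort from ", config$cohort_csv)
    cohort <- read_cohort_csv(config$cohort_csv)
  }

  n_missing_edi <- sum(is.na(cohort$edi))
  if (n_missing_edi > 0) {
    say("complete-case rule: dropping ", n_missing_edi,
        " record(s) with missing EDI")
    cohort <- cohort[!is.na(cohort$edi), , drop = FALSE]
  }
  write_cohort_csv(cohort, file.path(config$output_dir, "cohort.csv"))

  say("selecting structure by corrected AIC (M0/M1/M1b/M2)")
  sel <- select_structure(cohort, lt, k = config$knots,
                          n_nodes = config$n_nodes, aic = config$aic,
                          control = config$control)
  fit <- sel$selected_fit
  say("selected: ", sel$selected)
  utils::write.csv(sel$criteria,
                   file.path(config$output_dir, "table_selection.csv"),
                   row.names = FALSE)
  for (nm in names(sel$fits)) {
    write_fit_json(sel$fits[[nm]],
                   file.path(config$output_dir, paste0("fit_", nm, ".json")))
  }

  desc <- describe_cohort(cohort, fit)
  desc_df <- data.frame(
    n = desc$n, n_events = desc$n_events, median_age = desc$median_age,
    t(desc$quintile_share),
    ns_1m = desc$net_survival$surv[1], ns_1y = desc$net_survival$surv[2],
    ns_5y = desc$net_survival$surv[3]
  )
  utils::write.csv(desc_df,
                   file.path(config$output_dir, "table_descriptives.csv"),
                   row.names = FALSE)

  ehr <- if (sel$selected %in% c("M1b", "M2")) {
    compute_ehr(fit, age = config$reference_age, times = config$report_times,
                medians = config$medians)
  } else {
    compute_ehr(fit, age = config$reference_age, medians = config$medians)
  }
  if (sel$selected == "M0") ehr <- ehr[0, , drop = FALSE]  # no EDI effect
  utils::write.csv(as.data.frame(ehr),
                   file.path(config$output_dir, "table_ehr.csv"),
                   row.names = FALSE)

  grid <- seq(0, min(5, max(cohort$time_years)), length.out = 51)
  curves <- lapply(seq_along(config$medians), function(k) {
    cv <- predict_net_survival(fit, age = config$reference_age,
                               edi = config$medians[k], time_grid = grid)
    cv$quintile <- k
    as.data.frame(cv)
  })
  utils::write.csv(do.call(rbind, curves),
                   file.path(config$output_dir, "net_survival_curves.csv"),
                   row.names = FALSE)

  say("adequacy check against Pohar-Perme")
  adeq <- adequacy_check(fit, cohort, lt)
  if (isTRUE(adeq$comparable)) {
    utils::write.csv(
      data.frame(time = adeq$time, model = adeq$model,
                 pohar_perme = adeq$pohar_perme),
      file.path(config$output_dir, "adequacy.csv"), row.names = FALSE)
  }

  sens_summary <- NULL
  if (!is.null(config$sensitivity_ratios)) {
    say("sensitivity re-run under deprivation-stratified life tables")
    lt_strat <- build_deprivation_lifetables(
      lt, rate_ratio_table(config$sensitivity_ratios))
    sens <- sensitivity_rerun(cohort, lt, lt_strat,
                              age = config$reference_age,
                              medians = config$medians,
                              k = config$knots, n_nodes = config$n_nodes,
                              aic = config$aic, control = config$control)
    utils::write.csv(sens$comparison,
                     file.path(config$output_dir, "table_sensitivity.csv"),
                     row.names = FALSE)
    sens_summary <- sens$comparison
  }

  summary <- list(
    package_version = as.character(utils::packageVersion("netgradient")),
    config_hash = fingerprint,
    seed = config$seed,
    n = desc$n, n_events = desc$n_events,
    n_missing_edi_dropped = n_missing_edi,
    selected_structure = sel$selected,
    criteria = sel$criteria,
    edf_selected = fit$edf,
    net_survival = desc$net_survival,
    ehr = as.data.frame(ehr),
    adequacy_sup_distance = if (isTRUE(adeq$comparable)) adeq$sup_distance else NA,
    sensitivity = sens_summary
  )
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns")
  invisible(summary)
}
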