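# Typed model inputs: test performance, cohort, unit costs, pathway routing,
# outcome parameters. All user-facing model runs start from a validated
# `parameter_set`.

#' Diagnostic test performance
#'
#' Sensitivity and specificity of the serum spectroscopy test, with the
#' standard deviations of the classifier's iterated hold-out estimates
#' (used by the probabilistic sensitivity analysis to moment-match beta
#' distributions).
#'
#' @param sensitivity,specificity Proportions in \[0, 1\]. Defaults are the
#'   reported case-control estimates (0.928 and 0.915).
#' @param sd_sensitivity,sd_specificity Non-negative standard deviations;
#'   each must satisfy `sd^2 < m (1 - m)` so a beta distribution with those
#'   moments exists. Defaults 0.011 and 0.019.
#' @return An object of class `test_performance`.
#' @export
#' @examples
#' test_performance()
#' test_performance(sensitivity = 0.8, specificity = 0.8)
test_performance <- function(sensitivity = 0.928, specificity = 0.915,
                             sd_sensitivity = 0.011, sd_specificity = 0.019) {
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 sd_sensitivity = sd_sensitivity,
                 sd_specificity = sd_specificity),
            class = "test_performance")
}

#' Cohort specification
#'
#' @param size Number of patients entering the pathway (default 10,000, the
#'   reporting cohort of the base case).
#' @param prevalence Proportion with a brain tumour among those referred:
#'   0.005 in primary care, 0.03 in secondary care.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(size = 10000, prevalence = 0.005) {
  structure(list(size = size, prevalence = prevalence), class = "cohort_spec")
}

#' Unit-cost table
#'
#' Per-unit healthcare costs. UK values are 2015 NHS reference costs / PSSRU
#' prices in pounds; USA values are 2016 Medicare reimbursements in dollars.
#'
#' @param currency `"GBP"` or `"USD"`.
#' @param ct_scan,mri_scan Cost of a CT head / MRI brain with contrast study.
#' @param neurology_outpatient,gp_visit Cost of one clinic / GP visit.
#' @param monitoring_per_quarter Stable-disease monitoring cost per 3 months.
#' @param test_cost Price of one serum spectroscopy test (assumed bounds:
#'   UK 50--100, USA 100--200).
#' @param fast_track_premium Extra cost of a fast-tracked imaging episode over
#'   a routine one. Default 0 (the base model does not price fast-track
#'   imaging separately); exposed so users can explore the cost impact of the
#'   increased fast-track imaging volume generated by false positives.
#' @return An object of class `cost_table`.
#' @seealso [uk_cost_table()], [usa_cost_table()]
#' @export
cost_table <- function(currency, ct_scan, mri_scan, neurology_outpatient,
                       gp_visit, monitoring_per_quarter, test_cost,
                       fast_track_premium = 0) {
  structure(list(currency = currency, ct_scan = ct_scan, mri_scan = mri_scan,
                 neurology_outpatient = neurology_outpatient,
                 gp_visit = gp_visit,
                 monitoring_per_quarter = monitoring_per_quarter,
                 test_cost = test_cost,
                 fast_track_premium = fast_track_premium),
            class = "cost_table")
}

#' @rdname cost_table
#' @export
uk_cost_table <- function(test_cost = 50) {
  cost_table(currency = "GBP", ct_scan = 85, mri_scan = 164,
             neurology_outpatient = 35, gp_visit = 47.25,
             monitoring_per_quarter = 116, test_cost = test_cost)
}

#' @rdname cost_table
#' @export
usa_cost_table <- function(test_cost = 100) {
  cost_table(currency = "USD", ct_scan = 163, mri_scan = 380,
             neurology_outpatient = 76, gp_visit = 76,
             monitoring_per_quarter = 154, test_cost = test_cost)
}

#' Pathway routing parameters
#'
#' How patients move through the diagnostic pathway around the test.
#'
#' @param p_image_after_negative Proportion of test-negative patients who
#'   still proceed to imaging: 0.5 in primary care (a conservative clinical
#'   assumption), 1.0 in secondary care.
#' @param consultation_addon Extra consultation cost attached to a positive
#'   test result for discussion of the result (default 0; the scenario
#'   analysis sets it to the relevant visit cost).
#' @param survival_summary `"median"` (base case) or `"mean"`; which summary
#'   of diseased baseline survival feeds monitoring-cost and baseline-QALY
#'   terms. Increments are insensitive to this choice because baseline terms
#'   are identical in both arms.
#' @param delay_fast,delay_standard,delay_late Time-to-imaging in days for the
#'   delay classes D1 (fast track, 1 week), D2 (standard, 4 weeks) and D3
#'   (late/emergency, 8 weeks; reserved, not routed by default).
#' @param gp_visits,neuro_visits Visits per patient attached to a standard
#'   diagnostic work-up (defaults are set per care setting by
#'   [default_parameters()]: one GP visit in primary care, one neurology
#'   outpatient visit in secondary care).
#' @param imaging_mix Named proportions `c(ct = , mri = )` of the definitive
#'   imaging study; must sum to 1. Default 100% MRI (the definitive study is
#'   MRI brain with contrast).
#' @return An object of class `pathway_params`.
#' @export
pathway_params <- function(p_image_after_negative = 0.5,
                           consultation_addon = 0,
                           survival_summary = "median",
                           delay_fast = 7, delay_standard = 28,
                           delay_late = 56,
                           gp_visits = 1, neuro_visits = 0,
                           imaging_mix = c(ct = 0, mri = 1)) {
  structure(list(p_image_after_negative = p_image_after_negative,
                 consultation_addon = consultation_addon,
                 survival_summary = survival_summary,
                 delay_fast = delay_fast, delay_standard = delay_standard,
                 delay_late = delay_late,
                 gp_visits = gp_visits, neuro_visits = neuro_visits,
                 imaging_mix = imaging_mix),
            class = "pathway_params")
}

#' Outcome parameters
#'
#' Utility weight, horizon and the reduced-form calibrated quantities that
#' stand in for the unpublished survival-by-delay inputs.
#'
#' @param utility Health-state utility weight applied to life-years
#'   (base case 0.89, stable high-grade glioma).
#' @param horizon Model horizon in days (default 730; two years, chosen for
#'   the short survival of the modelled population).
#' @param qaly_gain_per_true_positive QALY gain `g` accruing to each diseased
#'   patient whose diagnosis is fast-tracked by a positive test. Calibrated
#'   (see [calibrate_gain()]); default recovered from the published
#'   secondary-care incremental QALYs.
#' @param avoided_cost_per_skipped_workup Cost `c_avoid` saved for each
#'   test-negative patient who does not proceed to the standard imaging
#'   work-up. Calibrated (see [calibrate_avoided_cost()]).
#' @param monitoring_cost_per_true_positive Extended-follow-up (stable-disease
#'   monitoring) cost `m` accrued on the extra survival of each true positive.
#'   `NULL` derives it analytically as `g / utility` life-years times the
#'   annualised monitoring rate; a number (the calibrated default, see
#'   [calibrate_monitoring_cost()]) uses that value directly.
#' @param discount_rate Annual discount rate applied to the second model year
#'   of survival-derived quantities. Default 0: no discounting is part of the
#'   base case and the published arithmetic is consistent with none.
#' @param baseline_survival_median,baseline_survival_mean Baseline survival of
#'   diseased patients in days under the median (365.25; median survival of
#'   high-grade glioma is about one year) or mean (456) summary. Used only for
#'   baseline monitoring-cost and baseline-QALY terms, which cancel in the
#'   incremental analysis.
#' @return An object of class `outcome_params`.
#' @export
outcome_params <- function(utility = 0.89, horizon = 730,
                           qaly_gain_per_true_positive = 0,
                           avoided_cost_per_skipped_workup = 0,
                           monitoring_cost_per_true_positive = NULL,
                           discount_rate = 0,
                           baseline_survival_median = 365.25,
                           baseline_survival_mean = 456) {
  structure(list(utility = utility, horizon = horizon,
                 qaly_gain_per_true_positive = qaly_gain_per_true_positive,
                 avoided_cost_per_skipped_workup = avoided_cost_per_skipped_workup,
                 monitoring_cost_per_true_positive = monitoring_cost_per_true_positive,
                 discount_rate = discount_rate,
                 baseline_survival_median = baseline_survival_median,
                 baseline_survival_mean = baseline_survival_mean),
            class = "outcome_params")
}

#' Bundle of all model inputs for one run
#'
#' @param test A [test_performance()] object.
#' @param cohort A [cohort_spec()] object.
#' @param costs A [cost_table()] object.
#' @param pathway A [pathway_params()] object.
#' @param outcomes An [outcome_params()] object.
#' @param scenario `"primary"` or `"secondary"` (care-setting entry point).
#' @param country `"UK"` or `"USA"`.
#' @param validate Validate the assembled set (default `TRUE`).
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(test, cohort, costs, pathway, outcomes,
                          scenario, country, validate = TRUE) {
  ps <- structure(list(test = test, cohort = cohort, costs = costs,
                       pathway = pathway, outcomes = outcomes,
                       scenario = scenario, country = country),
                  class = "parameter_set")
  if (validate) validate_parameters(ps)
  ps
}

# -- validation ---------------------------------------------------------------

chk <- function(findings, ok, path, msg) {
  if (!isTRUE(ok)) findings <- c(findings, sprintf("%s: %s", path, msg))
  findings
}

num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Validate a parameter set
#'
#' Checks every invariant of the component types and of the bundle as a
#' whole; stops with one message per violation, each naming the offending
#' field path (e.g. `cohort.prevalence`).
#'
#' @param params A [parameter_set()].
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  f <- parameter_findings(params)
  if (length(f) > 0)
    stop("invalid parameter_set:\n  ", paste(f, collapse = "\n  "),
         call. = FALSE)
  invisible(params)
}

#' @rdname validate_parameters
#' @return `parameter_findings()` returns a character vector of violations
#'   (empty when the set is valid).
#' @export
parameter_findings <- function(params) {
  f <- character(0)
  t <- params$test
  f <- chk(f, num1(t$sensitivity) && t$sensitivity >= 0 && t$sensitivity <= 1,
           "test.sensitivity", "must be a proportion in [0, 1]")
  f <- chk(f, num1(t$specificity) && t$specificity >= 0 && t$specificity <= 1,
           "test.specificity", "must be a proportion in [0, 1]")
  for (nm in c("sd_sensitivity", "sd_specificity")) {
    m <- if (nm == "sd_sensitivity") t$sensitivity else t$specificity
    f <- chk(f, num1(t[[nm]]) && t[[nm]] >= 0, paste0("test.", nm),
             "must be a non-negative number")
    if (num1(t[[nm]]) && num1(m) && t[[nm]] > 0 && m > 0 && m < 1)
      f <- chk(f, t[[nm]]^2 < m * (1 - m), paste0("test.", nm),
               "sd^2 must be < m(1-m) for a moment-matched beta to exist")
  }
  co <- params$cohort
  f <- chk(f, num1(co$size) && co$size > 0, "cohort.size", "must be > 0")
  f <- chk(f, num1(co$prevalence) && co$prevalence > 0 && co$prevalence < 1,
           "cohort.prevalence", "must be a proportion in (0, 1)")
  cs <- params$costs
  f <- chk(f, is.character(cs$currency) && cs$currency %in% c("GBP", "USD"),
           "costs.currency", "must be 'GBP' or 'USD'")
  for (nm in c("ct_scan", "mri_scan", "neurology_outpatient", "gp_visit",
               "monitoring_per_quarter", "test_cost", "fast_track_premium"))
    f <- chk(f, num1(cs[[nm]]) && cs[[nm]] >= 0, paste0("costs.", nm),
             "must be a non-negative number")
  pw <- params$pathway
  f <- chk(f, num1(pw$p_image_after_negative) &&
             pw$p_image_after_negative >= 0 && pw$p_image_after_negative <= 1,
           "pathway.p_image_after_negative", "must be a proportion in [0, 1]")
  f <- chk(f, num1(pw$consultation_addon) && pw$consultation_addon >= 0,
           "pathway.consultation_addon", "must be a non-negative number")
  f <- chk(f, is.character(pw$survival_summary) &&
             pw$survival_summary %in% c("median", "mean"),
           "pathway.survival_summary", "must be 'median' or 'mean'")
  f <- chk(f, num1(pw$delay_fast) && num1(pw$delay_standard) &&
             num1(pw$delay_late) &&
             pw$delay_fast < pw$delay_standard &&
             pw$delay_standard < pw$delay_late,
           "pathway.delay_fast", "delays must satisfy D1 < D2 < D3")
  f <- chk(f, num1(pw$gp_visits) && pw$gp_visits >= 0,
           "pathway.gp_visits", "must be a non-negative count")
  f <- chk(f, num1(pw$neuro_visits) && pw$neuro_visits >= 0,
           "pathway.neuro_visits", "must be a non-negative count")
  f <- chk(f, is.numeric(pw$imaging_mix) && length(pw$imaging_mix) == 2L &&
             all(sort(names(pw$imaging_mix)) == c("ct", "mri")) &&
             all(pw$imaging_mix >= 0) &&
             abs(sum(pw$imaging_mix) - 1) < 1e-9,
           "pathway.imaging_mix", "must be named proportions c(ct=, mri=) summing to 1")
  oc <- params$outcomes
  f <- chk(f, num1(oc$utility) && oc$utility >= 0 && oc$utility <= 1,
           "outcomes.utility", "must be a weight in [0, 1]")
  f <- chk(f, num1(oc$horizon) && oc$horizon > 0,
           "outcomes.horizon", "must be > 0 days")
  f <- chk(f, num1(oc$qaly_gain_per_true_positive) &&
             oc$qaly_gain_per_true_positive >= 0,
           "outcomes.qaly_gain_per_true_positive", "must be >= 0")
  f <- chk(f, num1(oc$avoided_cost_per_skipped_workup) &&
             oc$avoided_cost_per_skipped_workup >= 0,
           "outcomes.avoided_cost_per_skipped_workup", "must be >= 0")
  f <- chk(f, is.null(oc$monitoring_cost_per_true_positive) ||
             (num1(oc$monitoring_cost_per_true_positive) &&
                oc$monitoring_cost_per_true_positive >= 0),
           "outcomes.monitoring_cost_per_true_positive",
           "must be NULL (analytic) or >= 0")
  f <- chk(f, num1(oc$discount_rate) && oc$discount_rate >= 0,
           "outcomes.discount_rate", "must be >= 0")
  for (nm in c("baseline_survival_median", "baseline_survival_mean"))
    f <- chk(f, num1(oc[[nm]]) && oc[[nm]] > 0 && oc[[nm]] <= oc$horizon,
             paste0("outcomes.", nm), "must be in (0, horizon]")
  if (num1(oc$utility) && num1(oc$horizon) &&
      num1(oc$qaly_gain_per_true_positive)) {
    base_days <- baseline_survival_days(params)
    if (num1(base_days))
      f <- chk(f, oc$qaly_gain_per_true_positive <=
                 oc$utility * (oc$horizon - base_days) / 365.25 + 1e-9,
               "outcomes.qaly_gain_per_true_positive",
               "gain must fit within the horizon above baseline survival")
  }
  f <- chk(f, is.character(params$scenario) &&
             params$scenario %in% c("primary", "secondary"),
           "scenario", "must be 'primary' or 'secondary'")
  f <- chk(f, is.character(params$country) && params$country %in% c("UK", "USA"),
           "country", "must be 'UK' or 'USA'")
  f
}

baseline_survival_days <- function(params) {
  if (identical(params$pathway$survival_summary, "mean"))
    params$outcomes$baseline_survival_mean
  else params$outcomes$baseline_survival_median
}

# -- defaults -----------------------------------------------------------------

#' Base-case parameter set for one cell of the published results
#'
#' Assembles the fully populated base case for a care setting and country:
#' prevalence 0.5% (primary care) or 3% (secondary care), the country's
#' unit-cost column, sensitivity 0.928 / specificity 0.915, utility 0.89,
#' cohort of 10,000 patients, and the calibrated reduced-form outcome
#' quantities recovered from the published incremental results (see
#' [calibrate_gain()], [calibrate_monitoring_cost()] and
#' [calibrate_avoided_cost()]).
#'
#' In secondary care every test-negative patient continues to imaging
#' (`p_image_after_negative = 1`); in primary care half do.
#'
#' @param scenario `"primary"` or `"secondary"`.
#' @param country `"UK"` or `"USA"`.
#' @param test_cost Price per test; defaults to the lower assumed bound for
#'   the country (UK 50, USA 100).
#' @param calibrated Fill the reduced-form outcome quantities from the
#'   published increments (default `TRUE`). `FALSE` leaves them at zero, for
#'   users supplying their own.
#' @return A validated [parameter_set()].
#' @export
#' @examples
#' p <- default_parameters("secondary", "UK", test_cost = 50)
#' p$cohort$prevalence   # 0.03
#' p$costs$mri_scan      # 164
default_parameters <- function(scenario = c("primary", "secondary"),
                               country = c("UK", "USA"),
                               test_cost = NULL, calibrated = TRUE) {
  if (length(scenario) != 1L || !scenario %in% c("primary", "secondary"))
    stop("scenario: must be 'primary' or 'secondary'", call. = FALSE)
  if (length(country) != 1L || !country %in% c("UK", "USA"))
    stop("country: must be 'UK' or 'USA'", call. = FALSE)
  if (is.null(test_cost)) test_cost <- if (country == "UK") 50 else 100
  if (!num1(test_cost) || test_cost <= 0)
    stop("costs.test_cost: must be > 0", call. = FALSE)

  costs <- if (country == "UK") uk_cost_table(test_cost) else usa_cost_table(test_cost)
  primary <- scenario == "primary"
  ps <- parameter_set(
    test = test_performance(),
    cohort = cohort_spec(size = 10000,
                         prevalence = if (primary) 0.005 else 0.03),
    costs = costs,
    pathway = pathway_params(
      p_image_after_negative = if (primary) 0.5 else 1.0,
      gp_visits = if (primary) 1 else 0,
      neuro_visits = if (primary) 0 else 1),
    outcomes = outcome_params(),
    scenario = scenario, country = country, validate = FALSE)
  if (calibrated) ps <- apply_default_calibration(ps)
  validate_parameters(ps)
  ps
}

# Fill g, m and c_avoid from the published incremental results of this
# country (see calibrate_* for the anchors used).
apply_default_calibration <- function(params) {
  cal <- default_calibration(params$country)
  params$outcomes$qaly_gain_per_true_positive <- cal$g
  params$outcomes$monitoring_cost_per_true_positive <- cal$m
  params$outcomes$avoided_cost_per_skipped_workup <- cal$c_avoid
  params
}

#' Modify a single scalar model parameter by name
#'
#' Convenience used by the sensitivity-analysis machinery. Supported names:
#' `sensitivity`, `specificity`, `test_cost`, `prevalence`, `utility`,
#' `p_image_after_negative`.
#'
#' @param params A [parameter_set()].
#' @param name Parameter name.
#' @param value New value.
#' @return The modified, revalidated parameter set.
#' @export
set_parameter <- function(params, name, value) {
  field <- switch(name,
    sensitivity = c("test", "sensitivity"),
    specificity = c("test", "specificity"),
    test_cost = c("costs", "test_cost"),
    prevalence = c("cohort", "prevalence"),
    utility = c("outcomes", "utility"),
    p_image_after_negative = c("pathway", "p_image_after_negative"),
    stop("unknown parameter name: ", name, call. = FALSE))
  params[[field[1]]][[field[2]]] <- value
  validate_parameters(params)
  params
}

get_parameter <- function(params, name) {
  field <- switch(name,
    sensitivity = c("test", "sensitivity"),
    specificity = c("test", "specificity"),
    test_cost = c("costs", "test_cost"),
    prevalence = c("cohort", "prevalence"),
    utility = c("outcomes", "utility"),
    p_image_after_negative = c("pathway", "p_image_after_negative"),
    stop("unknown parameter name: ", name, call. = FALSE))
  params[[field[1]]][[field[2]]]
}

#' List the field paths on which two parameter sets differ
#'
#' Used to audit that a scenario toggle changes only the parameters it names.
#'
#' @param a,b Two [parameter_set()] objects.
#' @return Character vector of dotted field paths.
#' @export
parameter_diff <- function(a, b) {
  out <- character(0)
  for (grp in c("test", "cohort", "costs", "pathway", "outcomes")) {
    keys <- union(names(a[[grp]]), names(b[[grp]]))
    for (k in keys) {
      va <- a[[grp]][[k]]; vb <- b[[grp]][[k]]
      same <- (is.null(va) && is.null(vb)) ||
        (!is.null(va) && !is.null(vb) && length(va) == length(vb) &&
           isTRUE(all(va == vb)))
      if (!same) out <- c(out, paste(grp, k, sep = "."))
    }
  }
  if (!identical(a$scenario, b$scenario)) out <- c(out, "scenario")
  if (!identical(a$country, b$country)) out <- c(out, "country")
  out
}

#' @export
print.parameter_set <- function(x, ...) {
  cat(sprintf("<parameter_set> %s care, %s (%s)\n", x$scenario, x$country,
              x$costs$currency))
  cat(sprintf("  cohort: N = %g, prevalence = %g\n", x$cohort$size,
              x$cohort$prevalence))
  cat(sprintf("  test: sens = %.3f, spec = %.3f, cost = %.2f\n",
              x$test$sensitivity, x$test$specificity, x$costs$test_cost))
  cat(sprintf("  pathway: P(image | negative) = %g, survival summary = %s\n",
              x$pathway$p_image_after_negative, x$pathway$survival_summary))
  m <- x$outcomes$monitoring_cost_per_true_positive
  cat(sprintf("  outcomes: utility = %g, horizon = %g d, g = %.5f, c_avoid = %.2f, m = %s\n",
              x$outcomes$utility, x$outcomes$horizon,
              x$outcomes$qaly_gain_per_true_positive,
              x$outcomes$avoided_cost_per_skipped_workup,
              if (is.null(m)) "analytic" else sprintf("%.2f", m)))
  invisible(x)
}
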