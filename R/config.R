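# Config file loading and serialization. Schema: top-level keys
# scenario, country, test, cohort, costs, pathway, outcomes; leaf keys match
# the fields of the corresponding constructors. Unknown keys are rejected.

config_schema <- list(
  test = c("sensitivity", "specificity", "sd_sensitivity", "sd_specificity"),
  cohort = c("size", "prevalence"),
  costs = c("currency", "ct_scan", "mri_scan", "neurology_outpatient",
            "gp_visit", "monitoring_per_quarter", "test_cost",
            "fast_track_premium"),
  pathway = c("p_image_after_negative", "consultation_addon",
              "survival_summary", "delay_fast", "delay_standard",
              "delay_late", "gp_visits", "neuro_visits", "imaging_mix"),
  outcomes = c("utility", "horizon", "qaly_gain_per_true_positive",
               "avoided_cost_per_skipped_workup",
               "monitoring_cost_per_true_positive", "discount_rate",
               "baseline_survival_median", "baseline_survival_mean"))

#' Load a parameter set from a YAML or JSON config file
#'
#' The file starts from [default_parameters()] for its `scenario` and
#' `country` (defaults: primary care, UK) and overrides any fields it sets.
#' Unknown keys are rejected and every invariant is re-checked, with errors
#' naming the offending field path. An empty file yields the defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated [parameter_set()].
#' @seealso [write_config()] for the inverse; shipped example configs live in
#'   `system.file("extdata", "config", package = "spectriage")`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping: ", path, call. = FALSE)

  known_top <- c("scenario", "country", names(config_schema))
  bad <- setdiff(names(raw), known_top)
  if (length(bad) > 0)
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  for (grp in names(config_schema)) {
    if (is.null(raw[[grp]])) next
    if (!is.list(raw[[grp]]))
      stop(grp, ": must be a mapping of fields", call. = FALSE)
    bad <- setdiff(names(raw[[grp]]), config_schema[[grp]])
    if (length(bad) > 0)
      stop("unknown config key(s): ",
           paste(paste(grp, bad, sep = "."), collapse = ", "), call. = FALSE)
  }

  scenario <- raw$scenario %||% "primary"
  country <- raw$country %||% "UK"
  test_cost <- raw$costs$test_cost
  params <- default_parameters(scenario, country, test_cost = test_cost)
  for (grp in names(config_schema)) {
    if (is.null(raw[[grp]])) next
    for (k in names(raw[[grp]])) {
      v <- raw[[grp]][[k]]
      if (k == "imaging_mix") v <- unlist(v)
      if (is.integer(v)) storage.mode(v) <- "double"
      params[[grp]][[k]] <- v
    }
  }
  validate_parameters(params)
  params
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a parameter set to a config file
#'
#' JSON (default) preserves doubles exactly, so
#' `load_config(write_config(p, f))` round-trips `p`; YAML is also supported
#' for hand editing.
#'
#' @param params A [parameter_set()].
#' @param path Output path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  obj <- unclass_deep(params)
  obj$pathway$imaging_mix <- as.list(params$pathway$imaging_mix)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # I(17) = 17 significant digits: enough to round-trip any double exactly
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (is.list(v)) unclass_deep(v) else v)
}
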