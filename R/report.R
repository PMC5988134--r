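# Result tables: reproduction of the published base-case increments next to
# the package's own pipeline values, single-cell runs, CSV/JSON writers and
# run manifests.

#' Published base-case incremental results
#'
#' The published incremental QALYs, incremental costs and ICERs for cohorts
#' of 10,000 patients, by care setting, country and test price. These values
#' are model inputs: the calibration functions anchor the reduced-form
#' outcome quantities on them, and [base_case_table()] compares the pipeline
#' against them.
#'
#' @return A data frame with columns `scenario`, `country`, `test_cost`,
#'   `delta_qaly`, `delta_cost`, `icer`, `dominates`.
#' @export
reference_results <- function() {
  data.frame(
    scenario = rep(c("primary", "primary", "secondary", "secondary"), 2),
    country = rep(c("UK", "USA"), each = 4),
    test_cost = c(50, 100, 50, 100, 100, 200, 100, 200),
    delta_qaly = c(8.81, 8.81, 52.86, 52.86, 8.81, 8.81, 52.86, 52.86),
    delta_cost = c(-422116, 77884, 527646, 1027646,
                   -1718475, -218475, 536702, 2036702),
    icer = c(-47913, 8840, 9982, 19441, -195058, -24798, 10153, 38530),
    dominates = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' Run one base-case cell of the model
#'
#' Builds the default parameter set for a care setting, country and test
#' price (or uses a supplied one), runs the full pipeline and returns a
#' one-row result table.
#'
#' @param scenario `"primary"` or `"secondary"`.
#' @param country `"UK"` or `"USA"`.
#' @param test_cost Test price.
#' @param params Optional [parameter_set()] overriding the defaults.
#' @return A one-row data frame with the cell labels, `delta_qaly`,
#'   `delta_cost`, `icer` (unrounded), `icer_rounded` (reporting convention)
#'   and `dominance`.
#' @export
#' @examples
#' run_cell("secondary", "UK", 50)
run_cell <- function(scenario, country, test_cost, params = NULL) {
  if (is.null(params))
    params <- default_parameters(scenario, country, test_cost)
  res <- incremental(arm_pair(params))
  cbind(data.frame(scenario = scenario, country = country,
                   test_cost = test_cost, stringsAsFactors = FALSE),
        as_row(res))
}

#' Reproduce the published base-case table
#'
#' Runs every cell of the published base case (care setting x country x test
#' price) through the calibrated pipeline and places the package's values
#' side by side with the published ones, with match flags. Incremental QALYs
#' are compared at the published precision (2 decimal places), incremental
#' costs to the nearest currency unit, and ICERs after nearest-integer
#' rounding (half away from zero).
#'
#' The USA $100 column is known not to match on costs: both of its published
#' cost increments sit exactly $500,000 below the values implied by the
#' (internally consistent) $200 column, so the pipeline, which anchors on
#' the $200 column, reports the consistent values and flags the difference.
#'
#' @param country `"UK"`, `"USA"` or `"both"` (default).
#' @return A data frame with one row per cell: model values (`delta_qaly`,
#'   `delta_cost`, `icer_rounded`, `dominance`), published values
#'   (`ref_*`), and logical `match_dqaly`, `match_dcost`, `match_icer`,
#'   `match_icer_within_3` (the USA primary-care published ICERs differ from
#'   the quotient of their own published increments by 1--2 units, so those
#'   cells are held to the tolerance column rather than the exact one).
#' @export
base_case_table <- function(country = c("both", "UK", "USA")) {
  country <- match.arg(country)
  ref <- reference_results()
  if (country != "both") ref <- ref[ref$country == country, ]
  rows <- lapply(seq_len(nrow(ref)), function(i) {
    r <- ref[i, ]
    cell <- run_cell(r$scenario, r$country, r$test_cost)
    cell$ref_delta_qaly <- r$delta_qaly
    cell$ref_delta_cost <- r$delta_cost
    cell$ref_icer <- r$icer
    cell$ref_dominates <- r$dominates
    cell$match_dqaly <- round_half_away(cell$delta_qaly, 2) == r$delta_qaly
    cell$match_dcost <- abs(cell$delta_cost - r$delta_cost) < 0.5
    cell$match_icer <- cell$icer_rounded == r$icer
    cell$match_icer_within_3 <- abs(cell$icer_rounded - r$icer) <= 3
    cell
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a result table to CSV or JSON
#'
#' @param df A data frame (e.g. from [base_case_table()] or [run_cell()]).
#' @param path Output file; format chosen by extension (`.json` vs `.csv`).
#' @return `path`, invisibly.
#' @export
write_results <- function(df, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    write.csv(as.data.frame(df), path, row.names = FALSE)
  }
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run: the command, the resolved
#' parameter set, the package version, seeds and the emitted output files.
#' Re-running a command from its manifest reproduces deterministic outputs
#' bit-identically.
#'
#' @param command Command label (e.g. `"table2"`).
#' @param params The resolved [parameter_set()] (or `NULL`).
#' @param seed Seed(s) used, if any.
#' @param outputs Character vector of emitted file paths.
#' @param path Optional path to write the manifest JSON to.
#' @return The manifest list, invisibly if written.
#' @export
run_manifest <- function(command, params = NULL, seed = NULL,
                         outputs = character(0), path = NULL) {
  man <- list(
    command = command,
    package = "spectriage",
    version = as.character(utils::packageVersion("spectriage")),
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = if (!is.null(params)) unclass_deep(params),
    outputs = as.list(outputs))
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(man))
  }
  man
}
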