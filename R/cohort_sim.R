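# Patient-level microsimulation. Samples individual patients through the
# exact branch probabilities of the analytic tree, so any disagreement with
# rollback() is attributable to sampling alone; cohort means converge to the
# analytic expectations as the cohort grows.

#' Simulate a patient-level cohort through one model arm
#'
#' Builds the arm's decision tree with [build_arm()], enumerates its
#' root-to-leaf routes, and samples each patient's route from the exact leaf
#' probabilities. Payoffs are looked up from the tree's terminal nodes, not
#' re-derived. Deterministic for a given seed.
#'
#' @param params A validated [parameter_set()].
#' @param with_test Which arm to simulate.
#' @param seed Integer seed.
#' @return An object of class `cohort_table`: a data frame with one row per
#'   patient and columns `id`, `diseased`, `test_result`, `route`,
#'   `delay_class`, `received_imaging`, `cost`, `qaly`. The arm label, seed
#'   and parameter set are attached as attributes.
#' @export
#' @examples
#' p <- default_parameters("secondary", "UK", 50)
#' head(simulate_cohort(p, with_test = TRUE, seed = 7))
simulate_cohort <- function(params, with_test, seed) {
  validate_parameters(params)
  leaves <- tree_leaves(build_arm(params, with_test))
  probs <- vapply(leaves, `[[`, numeric(1), "prob")
  n <- params$cohort$size
  if (n != as.integer(n))
    stop("cohort.size: patient-level simulation needs an integer cohort size",
         call. = FALSE)
  set.seed(seed)
  idx <- sample.int(length(leaves), size = n, replace = TRUE, prob = probs)
  pick <- function(field, type) vapply(leaves, function(l)
    if (field %in% names(l$info)) l$info[[field]] else l[[field]], type)
  out <- data.frame(
    id = seq_len(n),
    diseased = pick("diseased", logical(1))[idx],
    test_result = pick("test_result", character(1))[idx],
    route = vapply(leaves, `[[`, character(1), "label")[idx],
    delay_class = pick("delay_class", character(1))[idx],
    received_imaging = pick("received_imaging", logical(1))[idx],
    cost = vapply(leaves, `[[`, numeric(1), "cost")[idx],
    qaly = vapply(leaves, `[[`, numeric(1), "qaly")[idx],
    stringsAsFactors = FALSE)
  attr(out, "arm") <- if (with_test) "with_test" else "without_test"
  attr(out, "seed") <- seed
  attr(out, "params") <- params
  class(out) <- c("cohort_table", class(out))
  out
}

#' Empirical summary of a simulated cohort
#'
#' Means, totals and per-route counts in the same shape as an `arm_outcome`
#' from [rollback()], with standard errors of the per-patient means.
#'
#' @param cohort A `cohort_table` from [simulate_cohort()].
#' @return An object of class `cohort_summary` with elements `expected_cost`,
#'   `expected_qaly` (cohort totals), `per_patient_cost`, `per_patient_qaly`,
#'   `se_per_patient_cost`, `se_per_patient_qaly`, `terminal_masses`
#'   (observed route counts) and `cohort_size`.
#' @export
summarize_cohort <- function(cohort) {
  n <- nrow(cohort)
  if (n == 0) stop("cohort: must be non-empty", call. = FALSE)
  sd0 <- function(x) if (n > 1) stats::sd(x) else 0
  structure(list(
    expected_cost = sum(cohort$cost),
    expected_qaly = sum(cohort$qaly),
    per_patient_cost = mean(cohort$cost),
    per_patient_qaly = mean(cohort$qaly),
    se_per_patient_cost = sd0(cohort$cost) / sqrt(n),
    se_per_patient_qaly = sd0(cohort$qaly) / sqrt(n),
    terminal_masses = table(cohort$route),
    cohort_size = n), class = "cohort_summary")
}

#' Write a simulated cohort to CSV
#'
#' One row per patient, columns in the documented order of
#' [simulate_cohort()].
#'
#' @param cohort A `cohort_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}
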