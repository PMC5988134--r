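# Incremental analysis: deltas, ICER, dominance, net monetary benefit.

#' Round half away from zero
#'
#' Reporting convention for ICERs: nearest integer currency unit with ties
#' rounded away from zero. This is the convention that reproduces every
#' internally consistent published ICER cell.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 0).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Incremental result from raw increments
#'
#' Computes the ICER `delta_cost / delta_qaly` and classifies dominance:
#' the intervention dominates iff it gains QALYs at negative incremental cost;
#' the comparator dominates iff the intervention loses QALYs at positive
#' incremental cost. The ICER is reported as a number only when
#' `delta_qaly != 0`; otherwise it is `NA` and flagged undefined (not a
#' division error). Dominance is reported alongside, never instead of, the
#' signed ICER.
#'
#' @param delta_cost Incremental cost (with test minus without), per cohort.
#' @param delta_qaly Incremental QALYs, per cohort.
#' @return An object of class `incremental_result` with elements
#'   `delta_cost`, `delta_qaly`, `icer`, `icer_defined`, `icer_rounded`
#'   (nearest integer, half away from zero) and `dominance` (`"none"`,
#'   `"intervention_dominates"` or `"comparator_dominates"`).
#' @export
#' @examples
#' incremental_result(527646, 52.86)$icer_rounded   # 9982
#' incremental_result(-422116, 8.81)$dominance      # intervention dominates
incremental_result <- function(delta_cost, delta_qaly) {
  defined <- delta_qaly != 0
  icer <- if (defined) delta_cost / delta_qaly else NA_real_
  dominance <- if (delta_qaly > 0 && delta_cost < 0) {
    "intervention_dominates"
  } else if (delta_qaly < 0 && delta_cost > 0) {
    "comparator_dominates"
  } else "none"
  structure(list(delta_cost = delta_cost, delta_qaly = delta_qaly,
                 icer = icer, icer_defined = defined,
                 icer_rounded = if (defined) round_half_away(icer) else NA_real_,
                 dominance = dominance),
            class = "incremental_result")
}

#' Incremental comparison of two rolled-back arms
#'
#' @param with_test,without_test `arm_outcome` objects from [rollback()] (or
#'   an [arm_pair()] may be passed as the first argument).
#' @return An `incremental_result`; see [incremental_result()].
#' @export
#' @examples
#' p <- default_parameters("secondary", "UK", 50)
#' incremental(arm_pair(p))
incremental <- function(with_test, without_test = NULL) {
  if (inherits(with_test, "arm_pair")) {
    without_test <- with_test$without_test
    with_test <- with_test$with_test
  }
  if (with_test$cohort_size != without_test$cohort_size)
    stop("arms were rolled back on different cohort sizes", call. = FALSE)
  incremental_result(with_test$expected_cost - without_test$expected_cost,
                     with_test$expected_qaly - without_test$expected_qaly)
}

#' Net monetary benefit
#'
#' `NMB(lambda) = lambda * delta_qaly - delta_cost`; positive iff the
#' intervention is cost-effective at willingness-to-pay `lambda`.
#'
#' @param result An `incremental_result`.
#' @param lambda Willingness-to-pay per QALY (vectorised, >= 0).
#' @return Net monetary benefit for each `lambda`.
#' @export
net_monetary_benefit <- function(result, lambda) {
  if (any(lambda < 0)) stop("lambda: must be >= 0", call. = FALSE)
  lambda * result$delta_qaly - result$delta_cost
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result>\n")
  cat(sprintf("  delta cost: %.2f\n  delta QALY: %.4f\n", x$delta_cost,
              x$delta_qaly))
  if (x$icer_defined) {
    cat(sprintf("  ICER: %.2f (reported %d)\n", x$icer,
                as.integer(x$icer_rounded)))
  } else {
    cat("  ICER: undefined (delta QALY is zero)\n")
  }
  if (x$dominance != "none") cat(sprintf("  dominance: %s\n", x$dominance))
  invisible(x)
}

as_row <- function(res) {
  data.frame(delta_qaly = res$delta_qaly, delta_cost = res$delta_cost,
             icer = res$icer, icer_rounded = res$icer_rounded,
             dominance = res$dominance, stringsAsFactors = FALSE)
}
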