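# Arm construction: confusion-matrix split of the cohort and the with-test /
# without-test decision trees for each care setting.

#' Expected confusion-matrix counts
#'
#' Expected (fractional) patient counts for a cohort tested once:
#' `tp = N p se`, `fn = N p (1 - se)`, `tn = N (1 - p) sp`,
#' `fp = N (1 - p) (1 - sp)`. The analytic model never rounds these; integer
#' patients live in [simulate_cohort()].
#'
#' @param cohort A [cohort_spec()].
#' @param test A [test_performance()].
#' @return An object of class `confusion_counts` with elements `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
#' @examples
#' confusion_counts(cohort_spec(10000, 0.03), test_performance())
confusion_counts <- function(cohort, test) {
  N <- cohort$size; p <- cohort$prevalence
  se <- test$sensitivity; sp <- test$specificity
  structure(list(tp = N * p * se, fn = N * p * (1 - se),
                 tn = N * (1 - p) * sp, fp = N * (1 - p) * (1 - sp)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp %.3f  fp %.3f  tn %.3f  fn %.3f\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

# Route table for one arm. The with-test arm splits by disease status and
# test result; positives are fast-tracked to imaging at D1, negatives proceed
# to the standard work-up at D2 with probability p_image_after_negative and
# otherwise skip it. The without-test arm is the current pathway: everyone is
# imaged at the standard delay D2 (diseased patients' baseline corresponds to
# the current median time to diagnosis).
arm_routes <- function(params, with_test) {
  if (!with_test) {
    return(list(
      route_spec("diseased_standard", "D2", receives_imaging = 1,
                 is_diseased = TRUE, tested = FALSE),
      route_spec("well_standard", "D2", receives_imaging = 1,
                 is_diseased = FALSE, tested = FALSE)))
  }
  list(
    tp = route_spec("tp_fast_track", "D1", receives_imaging = 1,
                    is_diseased = TRUE, tested = TRUE,
                    test_result = "positive", fast_track = TRUE,
                    extra_monitoring = TRUE),
    fn_img = route_spec("fn_imaging", "D2", receives_imaging = 1,
                        is_diseased = TRUE, tested = TRUE,
                        test_result = "negative"),
    fn_skip = route_spec("fn_no_imaging", "none", receives_imaging = 0,
                         is_diseased = TRUE, tested = TRUE,
                         test_result = "negative", skipped_workup = TRUE),
    fp = route_spec("fp_fast_track", "D1", receives_imaging = 1,
                    is_diseased = FALSE, tested = TRUE,
                    test_result = "positive", fast_track = TRUE),
    tn_img = route_spec("tn_imaging", "D2", receives_imaging = 1,
                        is_diseased = FALSE, tested = TRUE,
                        test_result = "negative"),
    tn_skip = route_spec("tn_no_imaging", "none", receives_imaging = 0,
                         is_diseased = FALSE, tested = TRUE,
                         test_result = "negative", skipped_workup = TRUE))
}

term_from_route <- function(route, params) {
  po <- terminal_payoff(route, params)
  terminal_node(route$label, cost = po$cost, qaly = po$qaly,
                info = list(diseased = route$is_diseased,
                            test_result = route$test_result,
                            delay_class = route$delay_class,
                            received_imaging = route$receives_imaging > 0))
}

# Chance node that collapses degenerate branches (probability 0 or 1) so the
# tree never contains a one-branch chance node.
branch_node <- function(label, probs, children) {
  keep <- probs > 0
  probs <- probs[keep]; children <- children[keep]
  if (length(children) == 1L) return(children[[1L]])
  chance_node(label, probs, children)
}

#' Build one model arm as a decision tree
#'
#' @param params A validated [parameter_set()].
#' @param with_test `TRUE` for the arm with the spectroscopy test inserted
#'   ahead of imaging, `FALSE` for the imaging-only comparator.
#' @return The root [chance_node()] of the arm.
#' @export
#' @examples
#' p <- default_parameters("secondary", "UK", 50)
#' build_arm(p, with_test = TRUE)
build_arm <- function(params, with_test) {
  validate_parameters(params)
  routes <- arm_routes(params, with_test)
  prev <- params$cohort$prevalence
  if (!with_test) {
    return(chance_node("presentation", c(prev, 1 - prev),
                       list(term_from_route(routes[[1]], params),
                            term_from_route(routes[[2]], params))))
  }
  se <- params$test$sensitivity
  sp <- params$test$specificity
  p_img <- params$pathway$p_image_after_negative
  neg_d <- branch_node("imaging_after_negative", c(p_img, 1 - p_img),
                       list(term_from_route(routes$fn_img, params),
                            term_from_route(routes$fn_skip, params)))
  neg_w <- branch_node("imaging_after_negative", c(p_img, 1 - p_img),
                       list(term_from_route(routes$tn_img, params),
                            term_from_route(routes$tn_skip, params)))
  diseased <- branch_node("test_result", c(se, 1 - se),
                          list(term_from_route(routes$tp, params), neg_d))
  well <- branch_node("test_result", c(1 - sp, sp),
                      list(term_from_route(routes$fp, params), neg_w))
  chance_node("presentation", c(prev, 1 - prev), list(diseased, well))
}

#' Roll back both arms of the comparison
#'
#' Builds and rolls back the with-test and without-test (imaging-only
#' comparator) arms on the identical cohort and parameters.
#'
#' @param params A validated [parameter_set()].
#' @return A list of class `arm_pair` with elements `with_test` and
#'   `without_test`, each an `arm_outcome`; the parameter set is attached as
#'   attribute `params`.
#' @export
arm_pair <- function(params) {
  out <- structure(
    list(with_test = rollback(build_arm(params, TRUE), params$cohort$size),
         without_test = rollback(build_arm(params, FALSE),
                                 params$cohort$size)),
    class = "arm_pair")
  attr(out, "params") <- params
  out
}
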