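# Deterministic sensitivity analyses: one-way grids, threshold search and the
# named scenario analyses.

OWSA_PARAMS <- c("sensitivity", "specificity", "test_cost", "prevalence",
                 "utility", "p_image_after_negative")

#' One-way sensitivity analysis
#'
#' Re-runs the full [arm_pair()] + [incremental()] pipeline at each grid
#' value of a single parameter, all others held at base.
#'
#' @param base A validated [parameter_set()].
#' @param parameter One of `sensitivity`, `specificity`, `test_cost`,
#'   `prevalence`, `utility`, `p_image_after_negative`.
#' @param grid Strictly increasing values within the parameter's valid range.
#' @return An object of class `owsa_curve`: a data frame with columns
#'   `value`, `delta_qaly`, `delta_cost`, `icer`, `icer_rounded`,
#'   `dominance`; the parameter name and base set are attached as attributes.
#' @export
#' @examples
#' p <- default_parameters("primary", "UK", 100)
#' owsa(p, "specificity", seq(0.80, 0.95, by = 0.05))
owsa <- function(base, parameter, grid) {
  if (!parameter %in% OWSA_PARAMS)
    stop("unknown parameter name: ", parameter, call. = FALSE)
  if (length(grid) < 1 || any(diff(grid) <= 0))
    stop("grid: must be strictly increasing", call. = FALSE)
  rows <- lapply(grid, function(v) {
    res <- incremental(arm_pair(set_parameter(base, parameter, v)))
    cbind(data.frame(value = v), as_row(res))
  })
  out <- do.call(rbind, rows)
  attr(out, "parameter") <- parameter
  attr(out, "base") <- base
  class(out) <- c("owsa_curve", class(out))
  out
}

icer_at <- function(base, parameter, value) {
  res <- incremental(arm_pair(set_parameter(base, parameter, value)))
  if (!res$icer_defined)
    stop("ICER undefined at ", parameter, " = ", value, call. = FALSE)
  res$icer
}

#' Threshold search on a single parameter
#'
#' Finds the parameter value at which the ICER crosses a willingness-to-pay
#' limit, by bisection to a parameter-space tolerance of `1e-4`. The ICER
#' must be monotone in the parameter over the bracket; this is checked on a
#' coarse grid and non-monotonicity is an error. Returns `NULL` when the
#' ICER never crosses the limit on the bracket (e.g. a configuration that is
#' dominant throughout).
#'
#' @param base A validated [parameter_set()].
#' @param parameter Parameter name (see [owsa()]).
#' @param icer_limit Willingness-to-pay threshold (cost per QALY).
#' @param lower,upper Bracket; defaults to a sensible range per parameter.
#' @param tol Bisection tolerance in parameter units.
#' @return The crossing value, or `NULL` if there is no crossing.
#' @export
find_threshold <- function(base, parameter, icer_limit,
                           lower = NULL, upper = NULL, tol = 1e-4) {
  default_range <- switch(parameter,
    sensitivity = c(0.5, 0.999), specificity = c(0.5, 0.999),
    test_cost = c(1, 500), prevalence = c(0.001, 0.2),
    utility = c(0.3, 1), p_image_after_negative = c(0, 1),
    stop("unknown parameter name: ", parameter, call. = FALSE))
  lower <- lower %||% default_range[1]
  upper <- upper %||% default_range[2]

  probe <- seq(lower, upper, length.out = 11)
  vals <- vapply(probe, function(v) icer_at(base, parameter, v), numeric(1))
  d <- diff(vals)
  if (any(d > 1e-9) && any(d < -1e-9))
    stop("ICER is not monotone in ", parameter, " over [", lower, ", ",
         upper, "]; no threshold returned", call. = FALSE)
  h <- vals - icer_limit
  if (all(h > 0) || all(h < 0)) return(NULL)

  lo <- lower; hi <- upper
  f_lo <- h[1]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- icer_at(base, parameter, mid) - icer_limit
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

SCENARIO_TOGGLES <- c("consultation_addon", "higher_imaging_after_negative",
                      "mean_survival", "prevalence_1pct")

#' Named scenario analyses
#'
#' Applies one of the named assumption toggles to a copy of the base set and
#' re-runs the pipeline:
#'
#' * `consultation_addon` — an additional consultation for discussion of a
#'   positive test result, priced at the care setting's visit cost (GP in
#'   primary care, neurology outpatient in secondary care);
#' * `higher_imaging_after_negative` — 75% (rather than 50%) of test-negative
#'   primary-care patients continue to imaging;
#' * `mean_survival` — mean rather than median baseline survival;
#' * `prevalence_1pct` — primary-care prevalence of 1% rather than 0.5%.
#'
#' @param base A validated [parameter_set()].
#' @param which One of the toggle names above.
#' @return An `incremental_result` with the modified parameter set attached
#'   as attribute `params`.
#' @export
scenario_analysis <- function(base, which) {
  if (!which %in% SCENARIO_TOGGLES)
    stop("unknown scenario name: ", which, call. = FALSE)
  params <- base
  if (which == "consultation_addon") {
    params$pathway$consultation_addon <-
      if (base$scenario == "primary") base$costs$gp_visit
      else base$costs$neurology_outpatient
  } else if (which == "higher_imaging_after_negative") {
    params$pathway$p_image_after_negative <- 0.75
  } else if (which == "mean_survival") {
    params$pathway$survival_summary <- "mean"
  } else if (which == "prevalence_1pct") {
    params$cohort$prevalence <- 0.01
  }
  validate_parameters(params)
  res <- incremental(arm_pair(params))
  attr(res, "params") <- params
  attr(res, "scenario_toggle") <- which
  res
}

#' Write an OWSA curve (one row per grid point) to CSV
#'
#' @param curve An `owsa_curve` from [owsa()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_owsa <- function(curve, path) {
  df <- as.data.frame(curve)
  df <- cbind(parameter = attr(curve, "parameter"), df)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
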