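# Probabilistic sensitivity analysis: moment-matched parameter distributions,
# seeded per-draw substreams, incremental-outcome clouds and CEACs.

#' Beta shape parameters from mean and standard deviation
#'
#' Moment matching: `alpha = m (m(1-m)/sd^2 - 1)`,
#' `beta = (1-m) (m(1-m)/sd^2 - 1)`. Requires `0 < sd^2 < m (1 - m)`.
#'
#' @param mean Mean in (0, 1).
#' @param sd Standard deviation.
#' @return Named vector `c(alpha, beta)`.
#' @export
#' @examples
#' beta_from_moments(0.928, 0.011)
beta_from_moments <- function(mean, sd) {
  if (mean <= 0 || mean >= 1)
    stop("mean: must be in (0, 1)", call. = FALSE)
  v <- sd^2
  if (v <= 0 || v >= mean * (1 - mean))
    stop("sd: need 0 < sd^2 < mean(1-mean) for a beta with these moments",
         call. = FALSE)
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma shape and rate from mean and standard deviation
#'
#' @param mean Positive mean.
#' @param sd Positive standard deviation.
#' @return Named vector `c(shape, rate)`.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (mean <= 0) stop("mean: must be > 0", call. = FALSE)
  if (sd <= 0) stop("sd: must be > 0", call. = FALSE)
  c(shape = mean^2 / sd^2, rate = mean / sd^2)
}

rbeta1 <- function(mean, sd) {
  if (sd == 0) return(mean)
  sh <- beta_from_moments(mean, sd)
  rbeta(1, sh["alpha"], sh["beta"])
}

rgamma1 <- function(mean, sd) {
  if (sd == 0 || mean == 0) return(mean)
  sh <- gamma_from_moments(mean, sd)
  rgamma(1, shape = sh["shape"], rate = sh["rate"])
}

#' PSA configuration
#'
#' Distribution choices follow standard practice for health-economic models:
#' beta distributions for probabilities and the utility weight (moment-matched
#' to the reported classifier SDs for sensitivity and specificity), gamma
#' distributions for unit costs and for the calibrated cost/effect quantities.
#' The test price is a decision variable, not an uncertain parameter, so it is
#' never sampled; this makes common-random-number comparisons across test
#' prices exact. The QALY gain per true positive carries the largest
#' uncertainty (it stands in for an unpublished natural-history model), hence
#' its wide default coefficient of variation.
#'
#' @param n_draws Number of Monte-Carlo draws (default 10,000).
#' @param seed Integer seed; each draw uses a substream keyed by
#'   `(seed, draw_index)`, so results are reproducible and order-independent.
#' @param lambda_grid Willingness-to-pay grid for the CEAC (default 0 to
#'   50,000 in steps of 1,000).
#' @param sd_utility SD of the utility-weight beta (default 0.03).
#' @param cv_prevalence CV of the prevalence beta (default 0.2).
#' @param cv_costs CV of the unit-cost gammas (default 0.2).
#' @param cv_gain CV of the per-true-positive QALY-gain gamma (default 0.5).
#' @param cv_avoided CV of the avoided-workup-cost gamma (default 0.2).
#' @return An object of class `psa_config`.
#' @export
psa_config <- function(n_draws = 10000, seed = 1,
                       lambda_grid = seq(0, 50000, by = 1000),
                       sd_utility = 0.03, cv_prevalence = 0.2,
                       cv_costs = 0.2, cv_gain = 0.5, cv_avoided = 0.2) {
  if (n_draws <= 0) stop("n_draws: must be > 0", call. = FALSE)
  if (length(lambda_grid) < 1 || any(lambda_grid < 0) ||
      any(diff(lambda_grid) <= 0))
    stop("lambda_grid: must be non-negative and strictly increasing",
         call. = FALSE)
  structure(list(n_draws = n_draws, seed = seed, lambda_grid = lambda_grid,
                 sd_utility = sd_utility, cv_prevalence = cv_prevalence,
                 cv_costs = cv_costs, cv_gain = cv_gain,
                 cv_avoided = cv_avoided),
            class = "psa_config")
}

# Deterministic substream seed for (seed, draw_index, attempt). The multiplier
# is coprime to 2^31 - 1, so distinct indices map to distinct seeds.
draw_seed <- function(seed, draw_index, attempt = 0) {
  as.integer((seed + draw_index * 506952114 + attempt * 97003) %% 2147483647L)
}

#' Sample one parameter set for the PSA
#'
#' Deterministic given `(config$seed, draw_index)`. Sensitivity and
#' specificity are drawn from betas moment-matched to their reported SDs;
#' utility and prevalence from betas; unit costs, the calibrated QALY gain
#' and the avoided-workup cost from gammas (see [psa_config()]). The
#' extended-follow-up cost per true positive is recomputed for each draw from
#' the drawn gain, utility and monitoring price, preserving the base-case
#' calibration ratio. A draw violating the parameter invariants is rejected
#' and resampled from a fresh substream (attempt count in attribute
#' `attempts`).
#'
#' @param config A [psa_config()].
#' @param base A validated [parameter_set()].
#' @param draw_index Draw number (1-based).
#' @return A validated [parameter_set()].
#' @export
draw_parameters <- function(config, base, draw_index) {
  for (attempt in 0:20) {
    set.seed(draw_seed(config$seed, draw_index, attempt))
    cand <- base
    cand$test$sensitivity <- rbeta1(base$test$sensitivity,
                                    base$test$sd_sensitivity)
    cand$test$specificity <- rbeta1(base$test$specificity,
                                    base$test$sd_specificity)
    cand$outcomes$utility <- rbeta1(base$outcomes$utility, config$sd_utility)
    cand$cohort$prevalence <- rbeta1(base$cohort$prevalence,
                                     config$cv_prevalence *
                                       base$cohort$prevalence)
    for (nm in c("ct_scan", "mri_scan", "neurology_outpatient", "gp_visit",
                 "monitoring_per_quarter"))
      cand$costs[[nm]] <- rgamma1(base$costs[[nm]],
                                  config$cv_costs * base$costs[[nm]])
    g0 <- base$outcomes$qaly_gain_per_true_positive
    cand$outcomes$qaly_gain_per_true_positive <-
      rgamma1(g0, config$cv_gain * g0)
    c0 <- base$outcomes$avoided_cost_per_skipped_workup
    cand$outcomes$avoided_cost_per_skipped_workup <-
      rgamma1(c0, config$cv_avoided * c0)
    m0 <- base$outcomes$monitoring_cost_per_true_positive
    if (!is.null(m0) && g0 > 0 && base$outcomes$utility > 0) {
      analytic0 <- (g0 / base$outcomes$utility) *
        annual_monitoring_rate(base$costs)
      kappa <- if (analytic0 > 0) m0 / analytic0 else 1
      cand$outcomes$monitoring_cost_per_true_positive <- kappa *
        (cand$outcomes$qaly_gain_per_true_positive / cand$outcomes$utility) *
        annual_monitoring_rate(cand$costs)
    }
    if (length(parameter_findings(cand)) == 0) {
      attr(cand, "attempts") <- attempt + 1L
      return(cand)
    }
  }
  stop("draw ", draw_index, ": could not sample a valid parameter set",
       call. = FALSE)
}

#' Run the probabilistic sensitivity analysis
#'
#' For each draw, samples a parameter set (see [draw_parameters()]) and runs
#' the full [arm_pair()] + [incremental()] pipeline on it.
#'
#' @param config A [psa_config()].
#' @param base A validated [parameter_set()].
#' @return An object of class `psa_result`: a data frame with one row per
#'   draw (sampled key parameters and incremental outcomes); `config` and
#'   `base` are attached as attributes.
#' @export
run_psa <- function(config, base) {
  rows <- vector("list", config$n_draws)
  for (i in seq_len(config$n_draws)) {
    ps <- draw_parameters(config, base, i)
    res <- incremental(arm_pair(ps))
    rows[[i]] <- data.frame(
      draw = i, sensitivity = ps$test$sensitivity,
      specificity = ps$test$specificity,
      prevalence = ps$cohort$prevalence, utility = ps$outcomes$utility,
      qaly_gain_per_true_positive = ps$outcomes$qaly_gain_per_true_positive,
      avoided_cost_per_skipped_workup =
        ps$outcomes$avoided_cost_per_skipped_workup,
      delta_cost = res$delta_cost, delta_qaly = res$delta_qaly,
      icer = res$icer, dominance = res$dominance,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- config
  attr(out, "base") <- base
  class(out) <- c("psa_result", class(out))
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of draws with strictly
#' positive net monetary benefit.
#'
#' @param results A `psa_result` from [run_psa()] (or any data frame with
#'   `delta_cost` and `delta_qaly` columns).
#' @param lambda_grid Willingness-to-pay grid; defaults to the grid in the
#'   result's PSA config.
#' @return An object of class `ceac_curve`: a data frame with columns
#'   `lambda`, `probability`, `n_draws`.
#' @export
ceac <- function(results, lambda_grid = NULL) {
  if (is.null(lambda_grid)) {
    cfg <- attr(results, "config")
    lambda_grid <- if (!is.null(cfg)) cfg$lambda_grid else seq(0, 50000, 1000)
  }
  if (nrow(results) == 0) stop("results: must be non-empty", call. = FALSE)
  prob <- vapply(lambda_grid, function(l)
    mean(l * results$delta_qaly - results$delta_cost > 0), numeric(1))
  out <- data.frame(lambda = lambda_grid, probability = prob,
                    n_draws = nrow(results))
  class(out) <- c("ceac_curve", class(out))
  out
}

#' Write a CEAC or PSA cloud to CSV
#'
#' @param x A `ceac_curve` or `psa_result`.
#' @param path Output file.
#' @param seed Optional seed recorded in a `seed` column of a CEAC file.
#' @return `path`, invisibly.
#' @export
write_ceac <- function(x, path, seed = NULL) {
  df <- as.data.frame(x)
  if (inherits(x, "ceac_curve") && !is.null(seed)) df$seed <- seed
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
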