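test_that("one-way grids rerun the pipeline with all else fixed", {
  p <- default_parameters("primary", "UK", 50)

  sp <- owsa(p, "specificity", seq(0.7, 0.99, length.out = 8))
  expect_equal(nrow(sp), 8)
  expect_equal(diff(sp$delta_qaly), rep(0, 7))     # QALYs blind to specificity
  expect_true(all(diff(sp$delta_cost) < 0))        # better specificity saves

  tc <- owsa(p, "test_cost", c(50, 100))
  expect_equal(tc$delta_cost[2] - tc$delta_cost[1], 500000)
  expect_equal(tc$delta_qaly[1], tc$delta_qaly[2])

  se <- owsa(p, "sensitivity", seq(0.8, 0.99, length.out = 6))
  expect_true(all(abs(diff(se$delta_qaly)) > 0))   # sensitivity moves both
  expect_true(all(abs(diff(se$delta_cost)) > 0))

  expect_error(owsa(p, "gravity", 1:3), "unknown parameter")
  expect_error(owsa(p, "specificity", c(0.9, 0.8)), "strictly increasing")
})

test_that("ICER is monotone non-increasing in specificity, increasing in price", {
  p <- default_parameters("primary", "UK", 100)
  icer_sp <- owsa(p, "specificity", seq(0.7, 0.99, length.out = 10))$icer
  expect_true(all(diff(icer_sp) <= 1e-9))

  grid <- seq(40, 140, by = 20)
  crv <- owsa(p, "test_cost", grid)
  expect_true(all(diff(crv$icer) > 0))
  # slope N / dQALY per unit of test cost
  slope <- diff(crv$icer) / diff(grid)
  expect_equal(slope, rep(10000 / crv$delta_qaly[1], length(slope)),
               tolerance = 1e-9)
})

test_that("threshold search brackets the willingness-to-pay crossing", {
  p <- default_parameters("primary", "UK", 100)
  thr <- find_threshold(p, "specificity", icer_limit = 30000,
                        lower = 0.7, upper = 0.99)
  expect_false(is.null(thr))
  expect_gt(thr, 0.7); expect_lt(thr, 0.95)
  # fixed point: the ICER recomputed at the threshold is at the limit
  at <- incremental(arm_pair(set_parameter(p, "specificity", thr)))$icer
  expect_lt(abs(at - 30000), 150)  # solver tolerance 1e-4 in parameter units

  # a configuration dominant over the whole range never crosses
  cheap <- default_parameters("primary", "UK", 30)
  expect_null(find_threshold(cheap, "specificity", icer_limit = 30000,
                             lower = 0.9, upper = 0.99))
})

test_that("scenario toggles change only the parameters they name", {
  p <- default_parameters("primary", "UK", 50)
  expected_fields <- list(
    consultation_addon = "pathway.consultation_addon",
    higher_imaging_after_negative = "pathway.p_image_after_negative",
    mean_survival = "pathway.survival_summary",
    prevalence_1pct = "cohort.prevalence")
  for (nm in names(expected_fields)) {
    res <- scenario_analysis(p, nm)
    expect_identical(parameter_diff(p, attr(res, "params")),
                     expected_fields[[nm]])
  }
  expect_error(scenario_analysis(p, "warp_drive"), "unknown scenario")
})

test_that("scenario analyses move the increments the expected way", {
  p <- default_parameters("primary", "UK", 50)
  base <- incremental(arm_pair(p))

  doubled <- scenario_analysis(p, "prevalence_1pct")
  expect_equal(doubled$delta_qaly, 2 * base$delta_qaly, tolerance = 1e-9)

  consult <- scenario_analysis(p, "consultation_addon")
  expect_equal(consult$delta_qaly, base$delta_qaly)
  expect_gt(consult$delta_cost, base$delta_cost)
  # cost moves by the positives' mass times the visit price
  cc <- confusion_counts(p$cohort, p$test)
  expect_equal(consult$delta_cost - base$delta_cost,
               (cc$tp + cc$fp) * p$costs$gp_visit, tolerance = 1e-7)

  more_imaging <- scenario_analysis(p, "higher_imaging_after_negative")
  expect_gt(more_imaging$delta_cost, base$delta_cost)
  expect_equal(more_imaging$delta_qaly, base$delta_qaly)

  robust <- scenario_analysis(p, "mean_survival")
  expect_equal(robust$delta_cost, base$delta_cost, tolerance = 1e-9)
  expect_equal(robust$delta_qaly, base$delta_qaly, tolerance = 1e-9)
})

test_that("OWSA curves export one CSV row per grid point", {
  p <- default_parameters("primary", "UK", 100)
  crv <- owsa(p, "specificity", seq(0.7, 0.99, length.out = 30))
  f <- file.path(withr::local_tempdir(), "owsa.csv")
  write_owsa(crv, f)
  got <- utils::read.csv(f)
  expect_equal(nrow(got), 30)
  expect_equal(got$parameter[1], "specificity")
})
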