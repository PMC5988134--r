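test_that("QALYs from survival apply the utility weight and horizon", {
  expect_equal(qaly_from_survival(365.25, 0.89, 730), 0.89)
  expect_equal(qaly_from_survival(1000, 1.0, 730), 730 / 365.25)  # truncation
  expect_equal(qaly_from_survival(0, 0.89, 730), 0)
  expect_error(qaly_from_survival(-1, 0.89, 730), "survival")
  expect_error(qaly_from_survival(100, 1.2, 730), "utility")
  # discounting reduces only the second model year
  expect_equal(qaly_from_survival(730, 1, 730, discount_rate = 0.035),
               1 + (730 / 365.25 - 1) / 1.035)
  expect_equal(qaly_from_survival(300, 1, 730, discount_rate = 0.035),
               300 / 365.25)
})

test_that("the QALY gain per true positive is identified by either scenario", {
  g2 <- calibrate_gain(52.86, cohort_spec(10000, 0.03), 0.928)
  expect_equal(g2, 52.86 / 278.4, tolerance = 1e-12)
  g1 <- calibrate_gain(8.81, cohort_spec(10000, 0.005), 0.928)
  expect_equal(g1, 8.81 / 46.4, tolerance = 1e-12)
  # cross-scenario consistency to 3 significant figures
  expect_equal(signif(g1, 3), signif(g2, 3))
  expect_equal(calibrate_gain(0, cohort_spec(10000, 0.03), 0.928), 0)
  expect_error(calibrate_gain(5, cohort_spec(10000, 0.03), 0), "true-positive")
})

test_that("extended-follow-up cost per true positive is recovered from costs", {
  m50 <- calibrate_monitoring_cost(527646, 50, cohort_spec(10000, 0.03), 0.928)
  m100 <- calibrate_monitoring_cost(1027646, 100, cohort_spec(10000, 0.03), 0.928)
  expect_equal(m50, 27646 / 278.4, tolerance = 1e-12)
  expect_equal(m50, m100)  # both published prices imply the same m
  # close to the analytic value: extra life-years x annualised monitoring
  analytic <- (52.86 / 278.4 / 0.89) * 4 * 116
  expect_equal(m50, analytic, tolerance = 0.005)
  expect_error(calibrate_monitoring_cost(400000, 50, cohort_spec(10000, 0.03),
                                         0.928), "negative")
})

test_that("avoided work-up cost solves the primary-care cost equation", {
  p <- default_parameters("primary", "UK", 50)
  c_avoid <- calibrate_avoided_cost(-422116, p)
  expect_equal(c_avoid, 203.5, tolerance = 1e-3)

  # zero-savings limit: a target equal to test cost plus monitoring term
  cc <- confusion_counts(p$cohort, p$test)
  fixed <- 10000 * 50 + cc$tp * (27646 / 278.4)
  expect_equal(calibrate_avoided_cost(fixed, p), 0)

  # not identifiable when every negative continues to imaging
  s2 <- default_parameters("secondary", "UK", 50)
  expect_error(calibrate_avoided_cost(527646, s2), "no skipped work-up")
})

test_that("terminal payoffs assemble the documented cost components", {
  p <- default_parameters("primary", "UK", 50)
  tp <- terminal_payoff(route_spec("tp", "D1", 1, TRUE, TRUE, "positive",
                                   fast_track = TRUE, extra_monitoring = TRUE),
                        p)
  m <- p$outcomes$monitoring_cost_per_true_positive
  expect_equal(unname(tp$components["test"]), 50)
  expect_equal(unname(tp$components["imaging"]), 164)   # 100% MRI mix
  expect_equal(unname(tp$components["visits"]), 47.25)
  # one baseline year of monitoring at 116/quarter is 464, plus the
  # calibrated extended-follow-up cost
  expect_equal(unname(tp$components["monitoring"]), 464 + m)
  expect_equal(tp$qaly, 0.89 + p$outcomes$qaly_gain_per_true_positive)

  skip_route <- route_spec("tn_skip", "none", 0, FALSE, TRUE, "negative",
                           skipped_workup = TRUE)
  tn <- terminal_payoff(skip_route, p)
  expect_equal(tn$cost, 50 + 164 + 47.25 -
                 p$outcomes$avoided_cost_per_skipped_workup)

  # consultation add-on attaches to positive results only
  p2 <- p; p2$pathway$consultation_addon <- 47.25
  expect_equal(terminal_payoff(route_spec("fp", "D1", 1, FALSE, TRUE,
                                          "positive", fast_track = TRUE),
                               p2)$components[["consultation"]], 47.25)
  expect_equal(terminal_payoff(skip_route, p2)$components[["consultation"]], 0)

  # imaging mix weights the scan cost
  p3 <- p; p3$pathway$imaging_mix <- c(ct = 0.4, mri = 0.6)
  well <- terminal_payoff(route_spec("well", "D2", 1, FALSE, FALSE), p3)
  expect_equal(unname(well$components["imaging"]), 0.4 * 85 + 0.6 * 164)
})

test_that("a test-cost change moves costs by N x delta and QALYs not at all", {
  set.seed(5)
  for (i in 1:5) {
    p <- random_params()
    delta <- stats::runif(1, 1, 80)
    r1 <- incremental(arm_pair(p))
    r2 <- incremental(arm_pair(set_parameter(
      p, "test_cost", p$costs$test_cost + delta)))
    expect_equal(r2$delta_cost - r1$delta_cost, p$cohort$size * delta,
                 tolerance = 1e-7)
    expect_equal(r2$delta_qaly, r1$delta_qaly)
  }
})

test_that("non-diseased QALYs cancel exactly in the increment", {
  set.seed(13)
  p <- random_params()
  # doubling the non-diseased QALY level (via horizon) must not move dQALY
  r1 <- incremental(arm_pair(p))
  p2 <- p
  p2$outcomes$horizon <- 1460
  validate_parameters(p2)
  r2 <- incremental(arm_pair(p2))
  expect_equal(r1$delta_qaly, r2$delta_qaly, tolerance = 1e-9)
})
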