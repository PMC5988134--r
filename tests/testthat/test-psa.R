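test_that("moment matching recovers the requested beta and gamma moments", {
  for (case in list(c(0.928, 0.011), c(0.915, 0.019), c(0.89, 0.03))) {
    sh <- beta_from_moments(case[1], case[2])
    m <- sh["alpha"] / (sh["alpha"] + sh["beta"])
    v <- sh["alpha"] * sh["beta"] /
      ((sh["alpha"] + sh["beta"])^2 * (sh["alpha"] + sh["beta"] + 1))
    expect_equal(unname(m), case[1], tolerance = 1e-10)
    expect_equal(unname(sqrt(v)), case[2], tolerance = 1e-10)
  }
  sh <- beta_from_moments(0.5, 0.05)
  expect_equal(unname(sh["alpha"]), unname(sh["beta"]))  # symmetric
  expect_error(beta_from_moments(0.9, 0.5), "sd")
  expect_error(beta_from_moments(1.2, 0.1), "mean")

  gm <- gamma_from_moments(116, 23.2)
  expect_equal(unname(gm["shape"] / gm["rate"]), 116)
  expect_equal(unname(sqrt(gm["shape"]) / gm["rate"]), 23.2)
})

test_that("parameter draws are deterministic in (seed, draw index)", {
  base <- default_parameters("primary", "UK", 50)
  cfg <- psa_config(n_draws = 10, seed = 99)
  a <- draw_parameters(cfg, base, 7)
  b <- draw_parameters(cfg, base, 7)
  expect_equal(a, b)
  c <- draw_parameters(cfg, base, 8)
  expect_false(identical(a$test$sensitivity, c$test$sensitivity))
  # the test price is a decision variable, never sampled
  expect_identical(a$costs$test_cost, base$costs$test_cost)
})

test_that("sampled sensitivity is centred on its base value", {
  base <- default_parameters("secondary", "UK", 50)
  cfg <- psa_config(n_draws = 3000, seed = 4)
  draws <- vapply(seq_len(3000), function(i)
    draw_parameters(cfg, base, i)$test$sensitivity, numeric(1))
  se <- 0.011 / sqrt(3000)
  expect_lt(abs(mean(draws) - 0.928), 4 * se)
  expect_equal(stats::sd(draws), 0.011, tolerance = 0.15)
})

test_that("degenerate distributions collapse the PSA to the base case", {
  base <- default_parameters("secondary", "UK", 50)
  base$test$sd_sensitivity <- 0
  base$test$sd_specificity <- 0
  cfg <- psa_config(n_draws = 3, seed = 1, sd_utility = 0, cv_prevalence = 0,
                    cv_costs = 0, cv_gain = 0, cv_avoided = 0)
  res <- run_psa(cfg, base)
  det <- incremental(arm_pair(base))
  expect_equal(res$delta_cost, rep(det$delta_cost, 3))
  expect_equal(res$delta_qaly, rep(det$delta_qaly, 3))
})

test_that("identical seeds reproduce the CEAC bit for bit", {
  base <- default_parameters("primary", "UK", 50)
  cfg <- psa_config(n_draws = 60, seed = 42)
  c1 <- ceac(run_psa(cfg, base))
  c2 <- ceac(run_psa(cfg, base))
  expect_identical(c1, c2)
})

test_that("CEAC definitions hold at the boundaries", {
  # all draws dominant: probability 1 at every willingness-to-pay
  dom <- data.frame(delta_cost = c(-10, -20), delta_qaly = c(1, 2))
  expect_equal(ceac(dom, seq(0, 10000, 1000))$probability,
               rep(1, 11))
  # at lambda = 0 the probability is the fraction of cost-saving draws
  mix <- data.frame(delta_cost = c(-10, 5, 3, -1), delta_qaly = rep(1, 4))
  expect_equal(ceac(mix, 0)$probability, 0.5)
  # a single draw with ICER 9982 steps from 0 to 1 between 9000 and 10000
  one <- data.frame(delta_cost = 527646, delta_qaly = 52.86)
  crv <- ceac(one, seq(0, 50000, 1000))
  expect_equal(crv$probability[crv$lambda <= 9000], rep(0, 10))
  expect_equal(crv$probability[crv$lambda >= 10000], rep(1, 41))
  expect_error(ceac(one[0, ]), "non-empty")
})

test_that("a dearer test is never more likely to be cost-effective", {
  cfg <- psa_config(n_draws = 120, seed = 7)
  c50 <- ceac(run_psa(cfg, default_parameters("secondary", "UK", 50)))
  c100 <- ceac(run_psa(cfg, default_parameters("secondary", "UK", 100)))
  # common random numbers make the pointwise ordering exact
  expect_true(all(c100$probability <= c50$probability))
})

test_that("CEAC files round-trip through the CSV writer", {
  cfg <- psa_config(n_draws = 20, seed = 3)
  crv <- ceac(run_psa(cfg, default_parameters("primary", "UK", 50)))
  f <- file.path(withr::local_tempdir(), "ceac.csv")
  write_ceac(crv, f, seed = 3)
  got <- utils::read.csv(f)
  expect_equal(got$probability, crv$probability)
  expect_equal(unique(got$seed), 3)
  expect_equal(unique(got$n_draws), 20)
})
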