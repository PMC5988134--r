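test_that("default parameter sets match the published base-case inputs", {
  cases <- list(
    list(scenario = "primary", country = "UK", test_cost = 50,
         prevalence = 0.005, p_img = 0.5, mri = 164, ct = 85, gp = 47.25),
    list(scenario = "secondary", country = "UK", test_cost = 50,
         prevalence = 0.03, p_img = 1.0, mri = 164, ct = 85, gp = 47.25),
    list(scenario = "primary", country = "USA", test_cost = 100,
         prevalence = 0.005, p_img = 0.5, mri = 380, ct = 163, gp = 76))
  for (cs in cases) {
    p <- default_parameters(cs$scenario, cs$country, cs$test_cost)
    expect_equal(p$cohort$prevalence, cs$prevalence)
    expect_equal(p$cohort$size, 10000)
    expect_equal(p$pathway$p_image_after_negative, cs$p_img)
    expect_equal(p$costs$mri_scan, cs$mri)
    expect_equal(p$costs$ct_scan, cs$ct)
    expect_equal(p$costs$gp_visit, cs$gp)
    expect_equal(p$test$sensitivity, 0.928)
    expect_equal(p$test$specificity, 0.915)
    expect_equal(p$outcomes$utility, 0.89)
    expect_equal(p$outcomes$horizon, 730)
  }
  expect_equal(default_parameters("secondary", "USA")$costs$monitoring_per_quarter, 154)
})

test_that("UK and USA defaults differ only in currency-bearing fields", {
  uk <- default_parameters("primary", "UK", 50)
  usa <- default_parameters("primary", "USA", 50)
  d <- parameter_diff(uk, usa)
  currency_bearing <- c(
    paste0("costs.", c("currency", "ct_scan", "mri_scan",
                       "neurology_outpatient", "gp_visit",
                       "monitoring_per_quarter")),
    "outcomes.monitoring_cost_per_true_positive",
    "outcomes.avoided_cost_per_skipped_workup",
    "country")
  expect_true(all(d %in% currency_bearing))
  # the calibrated QALY gain is a health quantity: identical across countries
  expect_equal(uk$outcomes$qaly_gain_per_true_positive,
               usa$outcomes$qaly_gain_per_true_positive)
})

test_that("validation errors name the offending field", {
  expect_error(default_parameters("tertiary", "UK", 50), "scenario")
  expect_error(default_parameters("primary", "France", 50), "country")
  expect_error(default_parameters("primary", "UK", -5), "test_cost")
  p <- default_parameters("primary", "UK", 50)
  p$cohort$prevalence <- 1.5
  expect_error(validate_parameters(p), "cohort\\.prevalence")
  p <- default_parameters("primary", "UK", 50)
  p$test$sd_specificity <- 0.6   # sd^2 > m(1-m): no beta exists
  expect_error(validate_parameters(p), "test\\.sd_specificity")
  p <- default_parameters("primary", "UK", 50)
  p$pathway$delay_standard <- 3  # violates D1 < D2 < D3
  expect_error(validate_parameters(p), "pathway\\.delay_fast")
})

test_that("set_parameter modifies exactly the named field and revalidates", {
  base <- default_parameters("primary", "UK", 50)
  for (nm in c("sensitivity", "specificity", "test_cost", "prevalence",
               "utility", "p_image_after_negative")) {
    mod <- set_parameter(base, nm, 0.75)
    expect_length(parameter_diff(base, mod), 1)
  }
  expect_error(set_parameter(base, "prevalence", 2), "cohort\\.prevalence")
  expect_error(set_parameter(base, "nonsense", 1), "unknown parameter")
})

test_that("config overrides start from defaults and reject bad input", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "cfg.yaml")

  writeLines("test:\n  specificity: 0.80", f)
  p <- load_config(f)
  base <- default_parameters("primary", "UK")
  expect_equal(p$test$specificity, 0.80)
  expect_equal(parameter_diff(base, p), "test.specificity")

  writeLines("", f)   # empty file: identical to the defaults
  expect_equal(load_config(f), base)

  writeLines("cohort:\n  prevalence: 1.5", f)
  expect_error(load_config(f), "cohort\\.prevalence")

  writeLines("cohort:\n  prevelance: 0.01", f)
  expect_error(load_config(f), "unknown config key")
  writeLines("typo_section:\n  a: 1", f)
  expect_error(load_config(f), "unknown config key")
  expect_error(load_config(file.path(dir, "absent.yaml")), "not found")
})

test_that("parameter sets round-trip exactly through JSON serialization", {
  p <- default_parameters("secondary", "USA", 200)
  f <- file.path(withr::local_tempdir(), "cfg.json")
  write_config(p, f)
  expect_identical(load_config(f), p)

  # YAML round-trips to working precision
  fy <- file.path(withr::local_tempdir(), "cfg.yaml")
  write_config(p, fy)
  expect_equal(load_config(fy), p, tolerance = 1e-12)
})

test_that("shipped base-case configs load and match default_parameters", {
  cfg_dir <- system.file("extdata", "config", package = "spectriage")
  expect_equal(load_config(file.path(cfg_dir, "secondary_uk.yaml")),
               default_parameters("secondary", "UK", 50))
  p1 <- load_config(file.path(cfg_dir, "primary_uk_prev1pct.yaml"))
  expect_equal(p1$cohort$prevalence, 0.01)
})
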