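# spectriage

Decision-tree cost-effectiveness modelling of a blood-serum spectroscopy
triage test for suspected brain tumour.

## The problem

Brain tumours present with non-specific symptoms (headache, dizziness, focal
deficits), the positive predictive value of symptoms alone is under 3%, and
definitive diagnosis needs MRI/CT imaging that cannot be fast-tracked for
everyone. The resulting delays — with a large share of diagnoses made in an
emergency setting — worsen prognosis in a disease whose median survival is
about a year for high-grade glioma. A rapid serum spectroscopy test
(sensitivity 92.8%, specificity 91.5% in case–control data) could triage
which patients are fast-tracked to imaging.

`spectriage` is an early health-economic evaluation of that test for
health-economics analysts: two decision-tree models (entry from **primary
care**, prevalence 0.5%, and **secondary care**, prevalence 3%) against the
current imaging-only pathway, over a two-year horizon from the
healthcare-service perspective, with UK (2015, £) and USA (2016, $) unit
costs.

## The model in brief

A cohort of N = 10,000 patients is split by disease status and test result;
test-positives are fast-tracked to imaging (1 week), test-negatives proceed
to the standard work-up (4 weeks) with probability 0.5 (primary care) or 1.0
(secondary care), otherwise skip it. Arms are valued by expected-value
rollback over (cost, QALY) payoffs, QALYs being utility-weighted life-years
(utility 0.89). Comparative value is the incremental cost-effectiveness
ratio

    ICER = (Cs − Cn) / (Hs − Hn)

(costs and QALYs with/without testing), with dominance (cheaper *and* more
effective) reported alongside, and net monetary benefit
NMB(λ) = λ·ΔQALY − ΔCost driving the probabilistic analysis.

Three reduced-form quantities that the published study derives from an
unavailable supplement are **calibrated** from its published incremental
results: the QALY gain per fast-tracked true positive (g ≈ 0.1899), the
extended-follow-up cost per true positive (£99.30 / $131.83) and the
avoided work-up cost per skipped test-negative (£203.50 / $488.50). See the
methods vignette (`vignettes/model-and-calibration.Rmd`) for why these are
exactly identified and for the known internal inconsistencies of the
published USA column.

On top of the deterministic model sit one-way and scenario sensitivity
analyses with threshold search, a seeded probabilistic sensitivity analysis
producing cost-effectiveness acceptability curves, and a patient-level
microsimulation used as a Monte-Carlo oracle for the analytic tree.

## Worked example

```r
library(spectriage)

p <- default_parameters("secondary", "UK", test_cost = 50)
p
#> <parameter_set> secondary care, UK (GBP)
#>   cohort: N = 10000, prevalence = 0.03
#>   test: sens = 0.928, spec = 0.915, cost = 50.00
#>   pathway: P(image | negative) = 1, survival summary = median
#>   outcomes: utility = 0.89, horizon = 730 d, g = 0.18987, c_avoid = 203.50, m = 99.30

incremental(arm_pair(p))
#> <incremental_result>
#>   delta cost: 527646.00
#>   delta QALY: 52.8600
#>   ICER: 9981.95 (reported 9982)
```

Testing 10,000 secondary-care patients at £50/test costs an extra £527,646
(the tests themselves plus monitoring over the extra survival of the 278.4
expected true positives) and gains 52.86 QALYs — £9,982 per QALY, well
inside the usual UK £20,000–£30,000 willingness-to-pay range. The full
base-case reproduction, side by side with the published values:

```r
base_case_table("UK")[, c("scenario", "test_cost", "delta_qaly",
                          "delta_cost", "icer_rounded", "dominance", "match_icer")]
#>    scenario test_cost delta_qaly delta_cost icer_rounded              dominance match_icer
#> 1   primary        50       8.81    -422116       -47913 intervention_dominates       TRUE
#> 2   primary       100       8.81      77884         8840                   none       TRUE
#> 3 secondary        50      52.86     527646         9982                   none       TRUE
#> 4 secondary       100      52.86    1027646        19441                   none       TRUE
```

At the lower test price in primary care the test *dominates* the current
pathway: it gains QALYs and saves £422,116 per 10,000 patients through
avoided imaging work-ups. Sensitivity and probabilistic analyses:

```r
owsa(p, "specificity", seq(0.7, 0.99, length.out = 10))   # QALYs never move
find_threshold(default_parameters("primary", "UK", 100),
               "specificity", icer_limit = 30000)

cfg <- psa_config(n_draws = 2000, seed = 1)
curve <- ceac(run_psa(cfg, p))                             # CEAC at £50

coh <- simulate_cohort(p, with_test = TRUE, seed = 7)      # 10,000 patients
summarize_cohort(coh)
```

A thin command-line front end ships in `inst/cli/spectriage`
(`run`, `table2`, `owsa`, `psa`, `simulate`, `calibrate` subcommands, each
writing a JSON manifest next to its output), and ready-made YAML configs for
every base case are in `inst/extdata/config/`.

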