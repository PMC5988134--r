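---
title: "The triage decision-tree model: structure, calibration and limits"
author: "spectriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The triage decision-tree model: structure, calibration and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectriage)
```

## The decision problem

Patients with symptoms that could indicate a brain tumour — non-specific
headache, focal neurological deficit — are referred for definitive MRI/CT
imaging either directly from primary care or via secondary-care neurology
clinics. Because the positive predictive value of symptoms alone is low,
imaging capacity cannot be fast-tracked for everyone, and diagnostic delays
(including a large share of diagnoses made in an emergency setting) worsen
prognosis in a disease whose median survival, for high-grade glioma, is about
one year.

A blood-serum spectroscopy test returning a result within a day offers a
triage mechanism: a positive result fast-tracks the patient to imaging, a
negative result makes a tumour unlikely and, in primary care, lets a share of
patients avoid an imaging work-up altogether. `spectriage` implements an
early (pre-trial) cost-effectiveness model of that triage test in two
scenarios:

* **primary care** — prevalence 0.5% among those who would be considered for
  direct-access imaging; after a negative test, 50% still proceed to imaging;
* **secondary care** — prevalence 3% among patients referred for imaging for
  suspected tumour; after a negative test, everyone still proceeds to imaging.

The comparator in both scenarios is the current imaging-only pathway. The
model is a one-shot decision tree over a two-year horizon (appropriate given
the short survival of the modelled population) from the healthcare-service
perspective, undiscounted by default (a discount rate is exposed as a
parameter but the base-case arithmetic is consistent with none). Health
outcomes are QALYs: utility-weighted life-years, with a stable-glioma utility
weight of 0.89.

## Tree structure

Each arm is a tree over the cohort of $N = 10{,}000$ patients. The with-test
arm splits by disease status (prevalence $p$), then by test result
(sensitivity $se = 0.928$, specificity $sp = 0.915$), then — for
test-negatives — by whether the patient proceeds to imaging (probability
$q$, the `p_image_after_negative` parameter):

```{r tree}
params <- default_parameters("primary", "UK", test_cost = 50)
build_arm(params, with_test = TRUE)
```

Test-positives are fast-tracked (delay class D1, one week); test-negatives
who image wait the standard four weeks (D2); the comparator arm images
everyone at D2. A late/emergency class D3 (eight weeks) is defined but not
routed by default: the share of emergency presentations is not quantified at
tree level in the published model, so attaching it would be an invention.
The expected confusion-matrix masses are kept fractional in the analytic
model; integer patients exist only in the microsimulation.

Terminal payoffs are `(cost, QALY)` pairs. Costs assemble the test price, an
optional consultation add-on for positive results, the imaging-mix-weighted
scan cost (default 100% MRI, the definitive study), GP/neurology visits (one
GP visit per work-up in primary care, one neurology outpatient visit in
secondary care — these cancel between arms), and stable-disease monitoring
over baseline survival for diseased patients. Non-diseased patients receive
the utility-weighted full horizon in both arms, so their QALYs cancel
exactly in the incremental comparison; this is deliberate, since the
published increments cannot depend on them.

Rollback is standard backward induction; branch probabilities must sum to
one within $10^{-9}$ and are never silently renormalised, because silent
renormalisation hides configuration mistakes. Expected terminal masses are
recorded for auditing and always sum to $N$.

## What is calibrated, and why

The published model rests on survival-by-delay curves and node-level
resource assumptions that appear only in an unavailable supplement. The
published incremental results, however, identify three reduced-form
quantities exactly, and those three are all the incremental analysis needs:

1. **QALY gain per true positive,** $g$. The two published incremental QALY
   values (8.81 and 52.86 per 10,000 patients) are exactly proportional to
   the true-positive masses of their scenarios ($46.4$ and $278.4$; note
   $52.86/8.81 = 278.4/46.4 = 6$). That forces the model form
   $\Delta\mathrm{QALY} = tp \times g$ — health effects flow entirely
   through earlier diagnosis of true positives, false negatives revert to
   the comparator pathway rather than a worse one, and incremental QALYs are
   invariant to specificity (a property the published sensitivity analysis
   states explicitly and the test suite asserts). Either scenario anchors
   $g = 52.86/278.4 \approx 0.1899$ QALYs, equivalent to about 78 days of
   utility-weighted survival.

2. **Extended-follow-up cost per true positive,** $m$. In secondary care the
   incremental cost decomposes as
   $\Delta C = N \cdot c_{test} + tp \cdot m$, so the published increments
   pin down $m = 27{,}646/278.4 \approx 99.30$ pounds (and $131.83$ dollars
   from the USA table). Deriving $m$ analytically instead — extra
   life-years $g/u$ times the annualised monitoring rate
   ($4 \times 116 = 464$ pounds/year) — gives 98.99, about 0.3% lower; the
   published cost and QALY increments are internally inconsistent at that
   level (likely printed rounding upstream), and no single survival-gain
   value reconciles both. We therefore calibrate $m$ as its own constant
   (the analytic derivation remains available by setting
   `monitoring_cost_per_true_positive = NULL`). Reassuringly, the UK and
   USA tables imply the same extra survival time (≈78.2 days) through
   their respective monitoring prices, which supports the
   rounding-residual interpretation.

3. **Avoided work-up cost per skipped patient,** $c_{avoid}$. In primary
   care a $1-q$ share of test-negatives skips the work-up, adding a
   $-\,\mathrm{skipped} \times c_{avoid}$ term; the published primary-care
   increment at the 50-pound test price solves to
   $c_{avoid} \approx 203.50$ pounds — plausibly an MRI plus most of a
   visit. The USA table solves to \$488.50. In secondary care the skipped
   mass is zero and the quantity is reported as not identifiable. In
   payoffs the credit is clamped so no route's net cost goes negative (a
   route cannot save more than it would have cost); the clamp never binds
   at base-case values.

USA calibration is anchored on the \$200 column: both published \$100 cost
increments sit *exactly* \$500,000 — that is, $N \times \$50$ — below the
values the \$200 column implies, in both scenarios, consistent with that
column having been computed at a \$50 test price. `base_case_table("USA")`
reports the internally consistent values and flags the differences rather
than reproducing the inconsistency. The published USA primary-care ICERs
also differ by 1–2 units from the quotient of their own published
increments; those cells are held to a ±3-unit tolerance.

With the three calibrated constants (two of them fitted per country), the
pipeline reproduces every published UK cell — incremental QALYs to two
decimals, costs to the pound, ICERs to the integer — and both coherent USA
columns:

```{r table2}
base_case_table("UK")[, c("scenario", "test_cost", "delta_qaly",
                          "delta_cost", "icer_rounded", "dominance")]
```

ICERs are reported rounded half-away-from-zero to the nearest currency
unit; that is the convention consistent with every internally coherent
published cell. Dominance (more effective *and* cheaper) is reported
alongside the signed ICER, never instead of it.

## Sensitivity analyses

`owsa()` re-runs the full pipeline over a grid of one parameter
(sensitivity, specificity, test cost, prevalence, utility or the
post-negative imaging probability). Structural consequences worth knowing:

* incremental QALYs never move with specificity; specificity acts only
  through costs (more true negatives, more avoided work-ups in primary
  care), so the ICER is monotone non-increasing in specificity;
* the ICER is linear in test price with slope $N/\Delta\mathrm{QALY}$;
* with the reduced-form $g$ held fixed, varying the utility weight does not
  move the increments: the calibrated QALY gain and the utility weight are
  treated as independently uncertain quantities rather than mechanically
  linked, since $g$ already absorbs the survival-gain evidence.

Because the specificity-dependence of costs runs through the calibrated
$c_{avoid}$ and the unpublished fast-track cost structure
(`fast_track_premium` defaults to 0, exposed for exploration), the absolute
specificity thresholds read off the published one-way-sensitivity figures
are not reproducible from the main results and are treated as qualitative
only. `find_threshold()` performs the corresponding bisection search against
this package's own cost structure, with monotonicity checked before
searching.

`scenario_analysis()` implements the four named assumption toggles:
consultation cost added to positive results (priced at the setting's visit
cost), 75% rather than 50% post-negative imaging in primary care, mean
rather than median baseline survival, and 1% primary-care prevalence. Each
toggle is audited to change only the parameter it names. Mean-survival
toggling leaves the increments unchanged by construction (baseline terms
cancel), matching the published robustness claim; the mean default of 456
days (~15 months, typical reported mean survival for high-grade glioma) only
affects absolute arm levels.

## Probabilistic sensitivity analysis

The published PSA distributions are in the unavailable supplement, so the
defaults here are standard health-economics practice, chosen once:

| quantity | family | spread |
|---|---|---|
| sensitivity, specificity | beta, moment-matched | reported SDs 0.011 / 0.019 |
| utility | beta | SD 0.03 |
| prevalence | beta | CV 0.2 |
| unit costs | gamma | CV 0.2 |
| QALY gain per TP ($g$) | gamma | CV 0.5 |
| avoided work-up cost | gamma | CV 0.2 |

The QALY gain carries the widest uncertainty because it stands in for an
unpublished natural-history model — by far the weakest link in a pre-trial
evaluation. The test price is a decision variable, not an uncertain
quantity, and is never sampled; combined with per-draw random-number
substreams keyed by `(seed, draw index)`, this makes CEACs at different
test prices comparable under common random numbers, so the curve at the
higher price lies at or below the curve at the lower price *pointwise and
exactly*, not just statistically. Draws violating any parameter invariant
are rejected and resampled from a fresh substream. The per-draw
extended-follow-up cost is recomputed from the drawn gain, utility and
monitoring price, preserving the base-case calibration ratio.

Under these defaults, at a willingness-to-pay of 30,000 pounds/QALY, the
probability that the test is cost-effective is near one in primary care and
roughly 0.9–0.95 in secondary care at the 50-pound price, dropping to
roughly 0.7–0.8 at 100 pounds — the qualitative pattern the published
acceptability curves show. These levels depend on the distribution choices
above and are asserted only as broad bands in the test suite, never as
exact reproductions.

## The microsimulation oracle

`simulate_cohort()` samples integer patients from the exact leaf
distribution of the analytic tree, so a disagreement with `rollback()` can
only come from sampling noise; the suite checks twenty random parameter
sets at $N = 100{,}000$ against a four-standard-error band, plus an
independently coded flat Bernoulli-chain sampler (disease → test result →
imaging decision) that does not share the tree code path at all. The
generator emulates cohort heterogeneity only along the tree's branches: it
does not model within-patient time-to-event beyond the delay class,
queueing or imaging capacity, or correlation between test performance and
disease severity. Passing these tests therefore validates the arithmetic of
the tree, not the clinical realism of its inputs.

## Numerical choices

* Probability tolerance $10^{-9}$ on chance nodes; renormalisation refused.
* ICERs rounded half away from zero for reporting; unrounded values always
  carried alongside.
* An ICER with zero incremental QALYs is undefined and flagged, not a
  division error.
* Calibrated constants are computed at load time from the committed
  published-results table (`reference_results()`), so the reproduction is a
  pure function of committed inputs with no hidden state.
* JSON serialization uses 17 significant digits so parameter sets round-trip
  exactly.
* Test problem sizes: 500 random trees for the rollback oracle, twenty
  parameter sets at $N = 10^5$ for the microsimulation oracle, a few hundred
  PSA draws for the distributional checks — sizes at which the Monte-Carlo
  bands are already decisive.

## Known limitations

* The routing defaults reconstruct the published tree from the main-text
  statements and the published increments; the original supplement's node
  probabilities may differ. Everything is exposed as configuration.
* False negatives are assigned the comparator pathway, not a worse one; the
  published model's specificity-invariance and cross-scenario
  proportionality force this, but it is an assumption, not evidence.
* No treatment-phase costing, no metastasis/primary stratification, no
  incidental-finding cascades, no currency conversion between the UK and
  USA settings, and no value-of-information analysis.
* The model is a one-shot tree: no state transitions, no cycles.
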