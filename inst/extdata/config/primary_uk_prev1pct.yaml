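# Alternative primary-care prevalence of 1% (direct-access imaging estimate),
# explored as a named configuration rather than a separate scenario.
scenario: primary
country: UK
costs:
  test_cost: 50
cohort:
  prevalence: 0.01
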