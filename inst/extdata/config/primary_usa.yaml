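# Base case: triage test in primary care, USA Medicare prices.
scenario: primary
country: USA
costs:
  test_cost: 100
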