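# Base case: triage test in secondary care (neuroimaging referral), UK prices.
scenario: secondary
country: UK
costs:
  test_cost: 50
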