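# Minimal generator configuration override: unspecified fields fall back
# to the package defaults (see ?generator_config).
n_children: 500
seed: 101
missing_rates:
  teacher_self_efficacy: 0.24
  attentional_regulation: 0.20
  parent_engagement: 0.18
mar_drivers:
- sep
- gender
mar_slopes:
  sep: -0.5
  gender: 0.25
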