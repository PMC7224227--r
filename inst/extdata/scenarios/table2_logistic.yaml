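# mortality for this family printed only for the exponential row (0.07/wk) and carried over here; initial populations unprinted. Absolute times not reproducible.
schema: 1
name: table2_logistic
description: 'growth-law benchmark, discrete-logistic row'
dt: 0.5
horizon: 600
extinction_threshold: 0.5
unreproducible_absolute_times: true
niches:
- initial: {ww: 10000, wv: 100, vv: 0.2}
  doubling_times: {ww: 5.9, wv: 11.8, vv: 5.9}
  death_rates: {ww: 0.07, vv: 0.07}
  dominance: dominant
  growth: logistic
  carrying_capacity: 100000
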