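# printed parameters give net-negative growth (ln2/11.6 < 0.07/wk), so the population never approaches capacity; initial populations for this family were never printed. Absolute event times are not reproducible.
schema: 1
name: table2_exponential
description: 'growth-law benchmark, exponential row'
dt: 0.5
horizon: 600
extinction_threshold: 0.5
unreproducible_absolute_times: true
niches:
- initial: {ww: 10000, wv: 100, vv: 0.2}
  doubling_times: {ww: 11.6, wv: 23.2, vv: 11.6}
  death_rates: {ww: 0.07, vv: 0.07}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
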