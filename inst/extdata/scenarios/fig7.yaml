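schema: 1
name: fig7
description: 'peripatric colonisation trajectory (two-niche, threshold migration until week 350)'
dt: 0.5
horizon: 1000
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 1, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.01, vv: 0.01}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
- initial: {ww: 0, wv: 0, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.99, vv: 0.01}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
migration:
  mode: threshold
  direction: one_way_1to2
  sf: {ww: 0.01, wv: 0.01, vv: 0.01}
  windows: [[0, 350]]
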