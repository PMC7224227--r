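schema: 1
name: table4_sim1
description: 'two-niche discrete-logistic benchmark row 1 (density migration)'
dt: 0.5
horizon: 1000
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 1, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.001, vv: 0.001}
  dominance: dominant
  growth: logistic
  carrying_capacity: 100000
- initial: {ww: 0, wv: 0, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.99, wv: 0.001, vv: 0.001}
  dominance: dominant
  growth: logistic
  carrying_capacity: 100000
migration:
  mode: density
  direction: one_way_1to2
  sf: {ww: 0.000001, wv: 1, vv: 1}
  windows: [[0, .inf]]
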