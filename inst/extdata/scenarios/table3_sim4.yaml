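# recessive mutation: heterozygotes share the wild-type's niche-2 mortality and no colonisation succeeds
schema: 1
name: table3_sim4
description: 'two-niche colonisation benchmark row 4 (threshold migration)'
dt: 0.5
horizon: 600
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 1, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.01, vv: 0.01}
  dominance: recessive
  growth: exponential
  carrying_capacity: 100000
# hostile to the ancestral karyotype
- initial: {ww: 0, wv: 0, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.99, vv: 0.01}
  dominance: recessive
  growth: exponential
  carrying_capacity: 100000
migration:
  mode: threshold
  direction: one_way_1to2
  sf: {ww: 0.01, wv: 0.01, vv: 0.01}
  windows: [[0, .inf]]
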