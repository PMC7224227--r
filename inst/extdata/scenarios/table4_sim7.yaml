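# mortality at the tipping point: the whole system declines to extinction; heterozygote niche-2 rate encodes the printed row, not the dominance rule
schema: 1
name: table4_sim7
description: 'two-niche discrete-logistic benchmark row 7 (density migration)'
dt: 0.5
horizon: 3400
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 1, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.07, vv: 0.07}
  dominance: dominant
  growth: logistic
  carrying_capacity: 100000
- initial: {ww: 1000, wv: 0, vv: 0}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.99, wv: 0.07, vv: 0.06}
  dominance: dominant
  growth: logistic
  carrying_capacity: 100000
migration:
  mode: density
  direction: two_way
  sf: {ww: 0.000001, wv: 1, vv: 1}
# reverse survival factors mirror the forward table: the wild-type is
# the genotype adapted to niche 1 (the per-direction table for the
# return journey was never printed)
  sf_reverse: {ww: 1, wv: 0.000001, vv: 0.000001}
  windows: [[0, .inf]]
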