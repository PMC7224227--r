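schema: 1
name: table1_sim07
description: 'single-niche benchmark row 7 (exponential-capped growth)'
dt: 0.5
horizon: 300
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 100, vv: 0.2}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.05, vv: 0.05}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
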