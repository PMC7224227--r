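# symmetric start: unstable 1:2:1 equilibrium, no extinction
schema: 1
name: table1_sim04
description: 'single-niche benchmark row 4 (exponential-capped growth)'
dt: 0.5
horizon: 1000
extinction_threshold: 0.5
niches:
- initial: {ww: 100, wv: 100, vv: 100}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.01, vv: 0.01}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
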