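schema: 1
name: fig5
description: 'growth-to-capacity trajectory of the canonical single-niche run'
dt: 0.5
horizon: 260
extinction_threshold: 0.5
niches:
- initial: {ww: 10000, wv: 100, vv: 0.2}
  doubling_times: {ww: 10, wv: 20, vv: 10}
  death_rates: {ww: 0.01, vv: 0.01}
  dominance: dominant
  growth: exponential
  carrying_capacity: 100000
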