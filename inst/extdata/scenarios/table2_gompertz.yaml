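# under per-class steady-state mortality, selection against heterozygotes fades near equilibrium and variant extinction does not complete; absolute times not reproducible.
schema: 1
name: table2_gompertz
description: 'growth-law benchmark, Gompertz row (density-dependent mortality)'
dt: 0.5
horizon: 3000
extinction_threshold: 0.5
unreproducible_absolute_times: true
niches:
- initial: {ww: 10000, wv: 100, vv: 0.2}
  doubling_times: {ww: 1.14, wv: 2.28, vv: 1.14}
  death_rates: {ww: 0, vv: 0}
  dominance: dominant
  growth: gompertz
  carrying_capacity: 100000
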