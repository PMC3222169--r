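# Default run configuration. All paths empty => packaged fixtures.
mode: deterministic          # deterministic | stochastic
population:
  which: audit               # audit | national | combined (population total)
scenarios:
  base: base_case
  alternative: alternative_1
paths: {}                    # population / catalog / scenarios / mortality CSVs
burden:
  conversion_factor: 0.18    # disability-weight shift per unit d
  cf_ci: [0.16, 0.20]
  attenuation: 0.20          # downward adjustment of all health gains
econ:
  wtp: 50000                 # euros per averted DALY
  wtp_grid: {from: 0, to: 50000, by: 1000}
psa:
  n_iterations: 500
  seed: 1
  sample_conversion_factor: true
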