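# Bundled small synthetic pipeline configuration used by the examples and
# the determinism test. Desk-scale: a 12 x 12 grid over 4 years.
seed: 7
grid:
  origin_lon: -10.0
  origin_lat: 12.0
  cellsize: 0.0416667
  n_cols: 12
  n_rows: 12
  years: {from: 2005, to: 2008}
simulate:
  n_covariates: 3
  n_monthly_covariates: 1
  field_sd: 0.5
  field_range: 0.15
  temporal_rho: 0.8
  noise_sd: 0.3
  n_sites: 60
  n_obs: 240
  n_vgsc: 30
level0:
  K: 4
  tune: false
  specs:
    gbt: {nrounds: 40, max_depth: 3}
    rf: {ntree: 40}
    bgam: {mstop: 60}
stack:
  n_draws: 150
predict:
  insecticides: [deltamethrin, DDT]
  protocol: WHO
summaries:
  threshold: 0.9
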