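# Example pipeline configuration (all keys optional; defaults shown in
# ?load_config).  Paths are resolved at run time.
seed: 7
paths:
  out_dir: ratescope_out
design:
  n_constructs: 4
  cells_per_construct: 30
  interval: 30        # minutes between images
  duration: 2880      # 48 h
constants:
  delta_M: 0.01
  delta_P: 0.0005
  alpha: 1
  kappa: 1
  sigma2: 40000
preprocess:
  threshold: 8000     # AU; keep traces with >= min_points samples above
  min_points: 10
  n_low: 30
  n_high: 35
mcmc:
  iterations: 50000
  burnin: 20000
  thin: 10
  chains: 2
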