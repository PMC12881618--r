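# Example overrides for the spiralpam pipeline. Any subset of the
# default_run_config() tree may appear here; unknown keys are rejected.
global:
  seed: 7
scanner:
  scan_frequency: 333
  max_radius: 0.0013
phantom:
  n_roots: 4
  tortuosity: 0.15
acquisition:
  prf_divisor: 200
  noise_sigma: 0.002
reconstruction:
  grid_size: 96
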