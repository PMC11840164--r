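# Demonstration pipeline configuration: a few noisy phantoms through the
# imaging chain and a published-size cohort through the statistics chain.
seed: 1
phantom:
  n_per_group: 2
  dims: [12, 12, 8]
  n_dir: 32
  bval: 1000
  noise: rician
  snr: 30
  axial: 1.4e-3
  radial: 4.0e-4
  alps_pd: 1.45
  alps_nc: 1.64
cohort:
  n_pd: 51
  n_nc: 30
analysis:
  alpha: 0.05
  n_boot: 1000
  level: 0.95
  mediators: [gmv_anterior_cingulate, gmv_orbital_inf_frontal]
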