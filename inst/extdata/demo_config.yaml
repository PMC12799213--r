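# Demonstration pipeline configuration (see ?run_config for defaults).
seed: 1
out_dir: ribbonquant_run
sim:
  n_pairs: 12
detection:
  surface_detail: 0.16
  min_voxels: 10
  volume_bounds: [0.02, 2.0]
  connectivity: 26
thresholds:
  pairing: 0.06
  syribbon: 0.045
costes:
  reps: 100
  block_px: 4
protocol:
  onset_frame: 11
  duration_frames: 10
  pre_frames: 5
  stim_avg_frames: 3
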