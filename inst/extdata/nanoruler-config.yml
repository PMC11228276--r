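# Example pipeline configuration: a 71-nm line-pair target imaged at low
# occupancy with a static focus.  Run with:
#   photonrestore pipeline --config nanoruler-config.yml
camera:
  rows: 64
  cols: 64
  pixel_size_nm: 20
  frame_interval_ms: 1
  read_noise_sigma: 2
  offset: 100
ii:
  gain_mean: 800
  gain_shape: 2
  spot_sigma: 1
psf:
  sigma_xy_nm: 110
  sigma_z_nm: 300
waveform:
  mode: static
emitters:
  geometry: line_pair
  spacing_nm: 71
  length_nm: 200
  pitch_nm: 5
  brightness: 0.02
  duration_ms: 2000
  center_nm: [640.0, 640.0, 0.0]
counting:
  k: 5
  method: gauss
  n_dark_frames: 300
reconstruct:
  voxel_xy_nm: 20
  n_iter: 200
  B: 50
  alpha: 0.05
seed: 1
outdir: nanoruler-out
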