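# Demo pipeline configuration: small synthetic sham/cTBS study with a
# coupling-decrease effect in the HCN-like network, analyzed at the
# standard thresholds. Output directory is supplied on the command line
# or via run_pipeline(config, out_dir).
seed: 7
simulate:
  n_subjects: 4
  n_frames: 100
  grid_shape: [18, 18, 10]
  conditions: [sham, cTBS]
  effects:
    - network: HCN
      block: [[4, 7], [4, 8], [4, 5]]
      conditions: [cTBS]
      coupling_delta: -0.44
networks: truth
contrasts:
  - [cTBS, sham]
settings:
  n_perm: 30
  voxel_z: 1.96
  driver_voxel_z: 3.291
  floor_voxels: 20
write_maps: false
write_runs: false
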