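# Example run_pipeline() configuration: one synthetic bilayer and one
# Metropolis particle system, all analyses, outputs under ./memlens_out.
seed: 1
output_dir: memlens_out
analyses: [membrane, cluster, rdf, pmf, minima, split, msd]
params:
  cluster: {cutoff: 1.30, window_frac: 0.5}
  rdf: {bin_width: 0.02, mode: plateau_normalized}
systems:
  - name: bilayer
    generator: membrane
    spec:
      n_lipids: 128
      box: [6.4, 6.4, 12.0]
      target_apl: 0.64
      head_separation: 4.0
      n_waters: 200
      sampler: {n_frames: 10}
  - name: particles
    generator: metropolis
    spec:
      n_particles: 24
      box: [10.0, 10.0, 10.0]
      pair_potential: {epsilon: 3.0, sigma: 0.9, cutoff: 1.2}
      temperature: 298
      sampler: {mode: metropolis, n_steps: 20000, step_size: 0.5, frame_stride: 20}
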