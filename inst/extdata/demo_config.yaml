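# Demo pipeline configuration: synthetic two-domain Parkin-like system at desk
# scale. Units: Angstrom, kcal/mol, ps, K.
system:
  n_residues: 465
  bond_length: 3.8
solvation:
  water_density: 1.0        # waters per 1000 A^3 of shell volume
potential: {}
equilibration:
  dt: 0.004
  heat_steps: 300
  min_iter: 150
  ramp_steps: 480
guideposts:
  n_posts: 5
  amplitude: 40            # RMS displacement of the flexible region, A
  n_modes: 3
demon:
  dt: 0.004
  thermostat: berendsen
  tau: 0.5
  T_target: 300
  com_removal_interval: 25
  sprint_min: 80
  sprint_max: 240
  accept_tol: 0.0
  success_radius: 3.0
  max_sprints: 400
  burn_in: 60
replicates:
  n_reps: 4
production:
  n_steps: 96000
  dt: 0.004
  thermostat: berendsen
  tau: 1.0
  T_target: 300
  save_stride: 240
  solvated: true
variants: [Ser65, pSer65, S65A, S65D, S65E]
metrics:
  pocket_cutoff: 5.0
  sasa_points: 240
  final_fraction: 0.3333333
ddg:
  maxit: 150
output_dir: demonmd_out
master_seed: 20140901
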