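# Double-well quickstart: the full pipeline on a 1D reduced-unit landscape.
# Barrier 8 kBT, Langevin friction 1, aimless shooting from the saddle.
seed: 7
output_dir: quickstart_out
system:
  potential_id: double_well_1d
  params:
    barrier: 8.0
cvs:
  - kind: coordinate_projection
    atom_indices: 1
    cv_id: x_1
basins:
  reactant:
    - cv_id: x_1
      comparator: "<"
      threshold: -0.8
  product:
    - cv_id: x_1
      comparator: ">"
      threshold: 0.8
shooting:
  T: 1.0
  dt: 0.005
  friction: 1.0
  max_steps: 5000
  n_chains: 8          # independent sampling schemes from the same saddle
  n_moves_per_chain: 40
  initial_x:
    - [0.0]
rc:
  method: ilmax
  inertial: true
committor:
  n_points: 40
  n_trials: 10
umbrella:
  range: auto          # extend past the RC values at reactive-trajectory endpoints
  width: 0.25
  k_restraint: 50.0
  n_replicas: 2
  n_steps: 3000
  reactant_side: auto  # lower quarter of the sampled RC range
kinetics:
  T: 310.0
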