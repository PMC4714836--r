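# Example run configuration: desk-scale 2D section, shear loading,
# tri-linear porosity law optimization.
scaffold:
  t: 2548
  h: 3822
  pore_rows: 5
  pore_cols: 3
  dimensionality: plane_strain_2d
  elem_size: 80
law:
  kind: trilinear
scaffold_E: 1000
load:
  kind: shear
  shear: 0.5
  ramp: 1.0
  steps: 10
optimizer:
  initial: 150
  fd_step: 20
  ftol: 0.01
  steptol: 2
  maxit: 15
  starts: [250]
seed: 1
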