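pes:
  type: model2d
  alpha1_L: 1.6
  alpha2_L: 4.0
  alpha1_R: 1.6
  alpha2_R: 4.0
  beta: 2.0
  theta: 0.2617993877991494
  d: 0.0
  m: 3.5
path:
  n_beads: 301
  tol: 1.0e-6
instanton:
  epsilon: 0.1
local:
  method: vci
  n_dvr: 8
  fit_order: 8
  basis_size: 7
  max_quanta: 6
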