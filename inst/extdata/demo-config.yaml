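# Illustrative orthotropic microtubule segment (values typical of the
# shell-model literature, not measurements of a specific experiment).
name: demo
geometry:
  L: 112 nm
  R: 11.2 nm
  h: 2.7 nm
  h0: 1.6 nm
material:
  E1: 1.5 GPa
  E2: 3 MPa
  G: 1.5 MPa
  mu1: 0.3
  mu2: 0.3
environment:
  Ec: 1 kPa
  ea0: 1.12 nm
  pressure: zero
modes:
  m_max: 25
  n_max: 8
sweep:
  axis: eta
  values: [0, 0.05, 0.1, 0.2]
output:
  dir: results
seed: 1
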