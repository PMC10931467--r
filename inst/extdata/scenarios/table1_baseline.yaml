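schema: 1
name: table1_baseline
note: >
  Baseline parameterisation. tau, alpha and phi are published as ranges
  (0.05-0.25, 0.3-0.5, 0.1-0.8); the baseline pins tau = 0.05 (low end),
  alpha = 0.4 (midpoint), phi = 0.45 (midpoint). Override freely.
parameters:
  Lambda: 0.5
  zeta: 0.35
  lam: 0.4
  tau: 0.05
  alpha: 0.4
  beta: 0.01
  chi: 0.25
  upsilon: 0.7
  sigma: 0.25
  omega: 0.8
  psi: 0.0027
  Phi: 0.7
  rho: 0.01
  phi: 0.45
initial_state: {S: 100, E: 1, I1: 5, I2: 2, R: 0, Q: 10}
integration: {h: 0.001, t_end: 500}
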