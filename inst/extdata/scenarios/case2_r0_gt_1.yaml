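schema: 1
name: case2_r0_gt_1
note: >
  Above-threshold scenario (R0 = 1.3372): the addiction persists at the
  endemic equilibrium (4.3123, 0.5588, 0.1799, 0.1055, 0.2013, 1.0055).
  The remaining parameters (omega, upsilon, rho, lam, zeta) keep their
  baseline values.
extends: table1_baseline
parameters:
  Lambda: 0.60556
  chi: 0.26104
  phi: 0.89339
  sigma: 0.22874
  Phi: 0.80142
  beta: 0.010014
  tau: 0.095
  alpha: 0.47155
  psi: 0.002909
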