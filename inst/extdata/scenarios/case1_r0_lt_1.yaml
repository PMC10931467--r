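schema: 1
name: case1_r0_lt_1
note: >
  Below-threshold scenario (R0 = 0.8684): addiction and depression die
  out and the population settles at the disease-free equilibrium
  (5, 0, 0, 0, 0, 0.5556).
extends: table1_baseline
parameters:
  tau: 0.09
  alpha: 0.5
  phi: 0.8
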