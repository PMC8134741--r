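model: integrator
params:
  v0: -65.0
  v1: -45.0
  v2: 55.0
  a0: 3.49999999999999995e-06
  a1: -0.0001
  v3: -35.0
  r0: 0.04
  r1: -0.004
  v4: -40.0
  v5: -5.0
  v6: -55.45000000000000284
  v7: 18.78000000000000114
  s0: 5.0
  s1: 7.59999999999999964
  s2: 1.80000000000000004
  k: 2
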