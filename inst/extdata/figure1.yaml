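# Classical Lotka-Volterra orbit: a = 2, b = c = 1, d = 3, start (4, 1).
seed: 1
mu:
  source: constant
  value: 1
macro:
  a: 2
  b: 1
  c: 1
  d: 3
  x0: 4
  y0: 1
  dt: 0.001
  t_end: 40
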