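# Hybrid orbit with closed-form learning functional (eta = 1/4), start (0.1, 9):
# with x0 << y0 the asymptotic closed orbit is reached more quickly.
seed: 1
mu:
  source: closed_form
  eta: 0.25
macro:
  a: 2
  b: 1
  c: 1
  d: 3
  x0: 0.1
  y0: 9
  dt: 0.001
  t_end: 40
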