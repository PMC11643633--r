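# Example simulation configuration: normal contractility on a stiffness
# gradient, middle start (70 kPa at the initial centroid), desk-scale grid.
grid:
  nx: 64
  ny: 64
  dx: 1.0
  dy: 1.0
substrate:
  kind: gradient
  E_ref: 70.0     # kPa at the domain centre (initial cell centroid)
  slope: 0.8      # kPa per micrometre, stiffer towards +y
  axis: y
params:
  flow:
    zeta: 0.002   # contractile strength (0 switches contractility off)
  dt: 0.25
run:
  n_steps: 4000
  record_every: 200
  seed: 1
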