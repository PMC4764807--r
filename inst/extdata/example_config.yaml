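# Example simulation configuration: wave emission from a spherical
# obstacle under a circularly polarized electric field, reduced scale.
model:
  a: 0.9
  b: 0.08
  epsilon: 0.02
  dx: 0.25
  grid: [60, 60, 60]
obstacle:
  radius: 2.5
  interface_width: 0.5
field:
  kind: CPEF
  E0: 1.8
  omega_e: 2.0
run:
  t_end: 40
  snapshot_every: 10
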