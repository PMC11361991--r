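breath:
  t_total: 6.0
  f_insp: 0.5
  a_rc: 5.0
  a_dim: 2.5
robot:
  shape: square
  level_kpa: 30.0
  k_transmission: 0.1
  t_inflate: 3.0
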