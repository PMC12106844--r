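# Example colonysim configuration: 10 mM glucose plate, small demonstration
# domain. Unspecified keys take the shipped defaults (see param_registry()).
metabolism:
  C_g_init: 10
numerics:
  domain_width: 720
  agar_depth: 480
  air_height: 60
  grid_h: 6
run:
  seed: 1
  t_end: 12
  snapshot_every: 2
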