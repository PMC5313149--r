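# Built-in cultivar parameter sets in the config-file dialect read by
# read_cultivar_config(). base_temp may be omitted (defaults by
# subspecies: japonica 10, indica 12).
YD6:
  subspecies: indica
  phyl_a: 0.0583
  phyl_b: 0.7936
  mmax_ssa3: 58.0
  final_rank: 15
W14:
  subspecies: japonica
  phyl_a: 0.0492
  phyl_b: 0.8062
  mmax_ssa3: 50.0
  final_rank: 15
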