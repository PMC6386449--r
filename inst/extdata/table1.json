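{
  "r_F": 0.121,
  "d_m": 0.002,
  "d_large": 0.198,
  "K_t": 15,
  "n": 2,
  "b_1": 0.122,
  "b_2": 0.009,
  "a_T": 0.000365,
  "d_c": 0.00028,
  "d_a": 0.00231,
  "F": 0.1,
  "D": 1,
  "v_cell": 6e-19
}
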