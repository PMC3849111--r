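branches:
- id: m_minus
  cell: m
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
- id: m_plus
  cell: m
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
- id: n_minus
  cell: 'n'
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
- id: n_plus
  cell: 'n'
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
nodes:
- id: gj
  kind: gap_junction
  R_MOhm: 100.0
  pair_m:
  - m_minus
  - m_plus
  pair_n:
  - n_minus
  - n_plus
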