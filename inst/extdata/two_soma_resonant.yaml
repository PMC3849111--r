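branches:
- id: c1.d1_p
  cell: c1
  length_um: 100.0
  prox_node: c1.soma
  dist_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c1.d1_d
  cell: c1
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c1.d2
  cell: c1
  length_um: inf
  prox_node: c1.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c1.d3
  cell: c1
  length_um: inf
  prox_node: c1.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c1.d4
  cell: c1
  length_um: inf
  prox_node: c1.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c2.d1_p
  cell: c2
  length_um: 100.0
  prox_node: c2.soma
  dist_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c2.d1_d
  cell: c2
  length_um: inf
  prox_node: gj
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c2.d2
  cell: c2
  length_um: inf
  prox_node: c2.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c2.d3
  cell: c2
  length_um: inf
  prox_node: c2.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
- id: c2.d4
  cell: c2
  length_um: inf
  prox_node: c2.soma
  diameter_um: 2.0
  C_uF_cm2: 1.0
  Ra_Ohm_cm: 100.0
  R_Ohm_cm2: 2000.0
  r_Ohm_cm2: 100.0
  L_H_cm2: 5.0
nodes:
- id: c1.soma
  kind: soma
  soma:
    as_um: 25.0
    Cs_uF_cm2: 1.0
    Rs_Ohm_cm2: 2000.0
    rs_Ohm_cm2: 1.0
    Ls_H_cm2: 0.1
- id: c2.soma
  kind: soma
  soma:
    as_um: 25.0
    Cs_uF_cm2: 1.0
    Rs_Ohm_cm2: 2000.0
    rs_Ohm_cm2: 1.0
    Ls_H_cm2: 0.1
- id: gj
  kind: gap_junction
  R_MOhm: 100.0
  pair_m:
  - c1.d1_p
  - c1.d1_d
  pair_n:
  - c2.d1_p
  - c2.d1_d
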