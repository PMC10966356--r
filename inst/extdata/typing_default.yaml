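# Default 21-type atomic polarizability classification.
# Roles are resolved in code: backbone = {N, C, O, OXT}; calpha = CA;
# amide_h = {H, HN, H1, H2, H3}; backbone_h = {HA, HA2, HA3};
# everything else = sidechain. The ss key is the residue's four-group
# class (H = helix, E = strand, C = coil, O = other); "*" matches any.
name: default-21
labels:
  - N_bb_H
  - N_bb_E
  - N_bb_C
  - N_bb_O
  - N_sc
  - C_bb_H
  - C_bb_E
  - C_bb_C
  - C_bb_O
  - C_sc
  - C_ca
  - O_bb_H
  - O_bb_E
  - O_bb_C
  - O_bb_O
  - O_sc
  - H_amide
  - H_bb
  - H_sc
  - S_sc
  - S_ss
rules:
  - {element: "N", role: backbone, ss: H, label: N_bb_H}
  - {element: "N", role: backbone, ss: E, label: N_bb_E}
  - {element: "N", role: backbone, ss: C, label: N_bb_C}
  - {element: "N", role: backbone, ss: O, label: N_bb_O}
  - {element: C, role: backbone, ss: H, label: C_bb_H}
  - {element: C, role: backbone, ss: E, label: C_bb_E}
  - {element: C, role: backbone, ss: C, label: C_bb_C}
  - {element: C, role: backbone, ss: O, label: C_bb_O}
  - {element: O, role: backbone, ss: H, label: O_bb_H}
  - {element: O, role: backbone, ss: E, label: O_bb_E}
  - {element: O, role: backbone, ss: C, label: O_bb_C}
  - {element: O, role: backbone, ss: O, label: O_bb_O}
  - {element: C, role: calpha, ss: "*", label: C_ca}
  - {element: H, role: amide_h, ss: "*", label: H_amide}
  - {element: H, role: backbone_h, ss: "*", label: H_bb}
  - {element: S, role: sidechain, ss: "*", label: S_ss, atom: SG}
fallback:
  H: H_sc
  C: C_sc
  "N": N_sc
  O: O_sc
  S: S_sc
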