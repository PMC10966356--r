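# Minimal 3-type classification by element, used for synthetic corpora
# built from heavy-atom-only fixtures (no H, no S in poly-alanine).
name: element-3
labels: [C_any, N_any, O_any]
rules:
  - {element: C, role: "*", ss: "*", label: C_any}
  - {element: "N", role: "*", ss: "*", label: N_any}
  - {element: O, role: "*", ss: "*", label: O_any}
fallback:
  H: C_any
  C: C_any
  "N": N_any
  O: O_any
  S: C_any
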