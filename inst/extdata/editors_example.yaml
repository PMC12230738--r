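# Example Cas variant and base editor definitions.
# Window positions are 1-based protospacer positions counted from the
# 5' (PAM-distal) end; edit is the substitution installed on the
# protospacer strand.
cas_variants:
  - name: SpCas9
    pam_patterns: [NGG]
  - name: SpG
    pam_patterns: [NGG, NGA, NGC, NGT]
base_editors:
  - name: BE4
    window: [4, 8]
    edit: "C>T"
    exclude_gc: false
  - name: evoAPOBEC1-BE4
    window: [4, 8]
    edit: "C>T"
    exclude_gc: true
  - name: ABE8e
    window: [4, 8]
    edit: "A>G"
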