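protein_id: RHO_synthetic
seq_length: 302
source: synthetic rhodopsin-like reference generated by make_toy_gpcr(toy_gpcr_spec(seed
  = 101)); not the published bovine rhodopsin boundaries
segments:
- label: N-term
  start: 0
  end: 25
- label: TM1
  start: 25
  end: 46
- label: ICL1
  start: 46
  end: 61
- label: TM2
  start: 61
  end: 82
- label: ECL1
  start: 82
  end: 97
- label: TM3
  start: 97
  end: 118
- label: ICL2
  start: 118
  end: 133
- label: TM4
  start: 133
  end: 154
- label: ECL2
  start: 154
  end: 169
- label: TM5
  start: 169
  end: 190
- label: ICL3
  start: 190
  end: 205
- label: TM6
  start: 205
  end: 226
- label: ECL3
  start: 226
  end: 241
- label: TM7
  start: 241
  end: 262
- label: C-term
  start: 262
  end: 302
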