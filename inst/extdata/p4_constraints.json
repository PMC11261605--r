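{
  "peptide": "P4",
  "d_strand": 4.6,
  "waxs": [
    {"d": 4.6, "present": true},
    {"d": 9.2, "present": true}
  ],
  "contacts": [
    {"a": "L28", "b": "F34", "bound": "lt", "threshold": 6.0}
  ]
}
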