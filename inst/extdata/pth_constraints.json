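{
  "peptide": "PTH25-37",
  "waxs": [
    {"d": 4.7, "present": true},
    {"d": 10.3, "present": true},
    {"d": 9.4, "present": false}
  ],
  "contacts": [
    {"a": "L28", "b": "F34", "bound": "gt", "threshold": 6.0}
  ]
}
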