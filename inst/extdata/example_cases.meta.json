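{
  "format": "dentplan-cases",
  "version": "1.0.0",
  "n_cases": 3,
  "finding_index": {
    "f": 0, ".": 1, "x": 2, "k": 3, "b": 4,
    "e": 5, "ww": 6, "kw": 7, "bw": 8, "ew": 9
  },
  "plan_index": { "-": 0, "K": 1, "B": 2, "E": 3 }
}
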