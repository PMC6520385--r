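{
  "sim": {
    "n_probes": 2000,
    "seed": 42,
    "planted_markers": [
      {
        "probe": "P00001",
        "gene": "SWITCH1",
        "targets": { "ectoderm": 0.9, "mesoderm": -0.9, "endoderm": -0.9 }
      }
    ]
  },
  "alpha": 0.05,
  "min_present": 4,
  "min_ratio": 5,
  "q_threshold": 0.05,
  "lfc_threshold": 0.6,
  "stages": { "filter": true, "rank": true, "screen": true, "methylation": true }
}
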