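{
  "frames_manifest": "bridge_manifest.csv",
  "r": 0.02,
  "D": 6272,
  "h": 1,
  "bc": "neumann",
  "ccfrac": 0.1,
  "seed_center": [4, 3],
  "seed_sigma": 2,
  "seed_peak": 0.9
}
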