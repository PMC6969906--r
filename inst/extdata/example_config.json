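{
  "canvas": [800, 800],
  "spacing": 10,
  "lesions": [
    {"x0": 300, "y0": 420, "R": 250, "D": 125, "variant": "cap"}
  ],
  "psychometric": {"threshold_delta": 0.01, "lapse_rate": 0, "guess_rate": 0},
  "theta": 0,
  "output_dir": "ngrid-run",
  "seed": 1
}
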