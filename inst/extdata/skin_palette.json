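{
  "comment": "Default skin palette: light-to-dark skin tones plus pigmented-nevus browns. Per-channel tolerance. Fully user-overridable.",
  "colors": [
    [236, 188, 168],
    [224, 172, 150],
    [208, 156, 130],
    [190, 140, 115],
    [170, 120, 95],
    [150, 105, 85],
    [130, 88, 68],
    [110, 72, 55],
    [95, 62, 48],
    [80, 52, 40],
    [60, 40, 30],
    [200, 170, 145]
  ],
  "tolerance": 40
}
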