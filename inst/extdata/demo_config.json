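{
  "phantom": {
    "grid_shape": [48, 48],
    "myo_radii_px": [10, 16],
    "lv_radius_px": 8,
    "territory_mbf": {"LAD": 1.4, "LCX": 2.0, "RCA": 2.0},
    "snr": 20,
    "seed": 7
  },
  "modes": ["none", "pd", "ssfp"],
  "diseased": ["LAD"],
  "seed": 7,
  "n_baseline": 4,
  "log_level": "info"
}
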