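{
  "control": "control",
  "scenarios": [
    {"label": "control", "bg": 1.2, "K": 1, "n": "inf",
     "noise_cv": 0.12, "n_embryos": 30, "hatch_prob": 0.92,
     "n_viability": 150},
    {"label": "no_feedback", "bg": 0.71, "K": "inf", "n": "inf",
     "noise_cv": 0.12, "n_embryos": 30, "hatch_prob": 0.1,
     "n_viability": 150},
    {"label": "category2_mutant", "bg": 0.73, "K": 1, "n": "inf",
     "noise_cv": 0.12, "n_embryos": 30, "hatch_prob": 0.7,
     "n_viability": 150},
    {"label": "category3_mutant", "bg": 0.5, "K": 1.5, "n": "inf",
     "noise_cv": 0.12, "n_embryos": 30, "hatch_prob": 0.55,
     "n_viability": 150}
  ],
  "thresholds": {
    "category": [0.9, 0.6],
    "alpha": 0.05,
    "n_boot": 20000,
    "domain_threshold": 0.5,
    "smooth_px": 3
  },
  "seed": 1,
  "out_dir": "snadosage_demo_out",
  "plots": false
}
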