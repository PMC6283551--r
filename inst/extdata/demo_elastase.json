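{
  "seed": 1,
  "simulator": {
    "n_clones": 20000,
    "rounds": 5,
    "n_sampled": 96,
    "model": {
      "admissible_p1": ["V", "A", "I"],
      "subsite_masses": {
        "P1": {"V": 0.4, "I": 0.35, "A": 0.25},
        "P1'": {"S": 0.15, "T": 0.15, "M": 0.1}
      },
      "site_efficiency_scale": 6e10,
      "background_release": 0.001
    }
  },
  "panel": {"threshold": 0.2},
  "alignment": {"p1_set": "called", "arm_policy": "mask"},
  "profile": {"frame": "P4-P4'"}
}
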