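{
  "seed": 1,
  "simulator": {
    "n_clones": 20000,
    "rounds": 5,
    "n_sampled": 96,
    "model": {
      "admissible_p1": ["F", "Y", "W"],
      "subsite_masses": {
        "P1": {"F": 0.3333333333, "Y": 0.3333333333, "W": 0.3333333334},
        "P2'": {"D": 0.25, "E": 0.25}
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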