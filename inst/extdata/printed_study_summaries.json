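{
  "description": "Published group and paired summary statistics of the reference two-group pre/post quasi-experiment (intervention n=9, control n=12). Paired entries are pre-minus-post change summaries.",
  "groups": {
    "pre_eh": {
      "control": {"mean": 25.83, "sd": 5.27, "n": 12},
      "intervention": {"mean": 23.33, "sd": 3.08, "n": 9}
    },
    "pre_hba1c": {
      "control": {"mean": 7.13, "sd": 1.49, "n": 12},
      "intervention": {"mean": 8.13, "sd": 2.83, "n": 9}
    },
    "post_eh": {
      "control": {"mean": 26.08, "sd": 2.94, "n": 12},
      "intervention": {"mean": 24.33, "sd": 3.54, "n": 9}
    },
    "post_hba1c": {
      "control": {"mean": 6.90, "sd": 1.64, "n": 12},
      "intervention": {"mean": 6.72, "sd": 1.27, "n": 9}
    },
    "nse": {
      "control": {"mean": 15.25, "sd": 3.22, "n": 12},
      "intervention": {"mean": 14.67, "sd": 1.66, "n": 9}
    }
  },
  "paired": {
    "hba1c": {
      "intervention": {"mean_diff": 1.41, "sd_diff": 1.75, "n": 9},
      "control": {"mean_diff": 0.23167, "sd_diff": 0.62, "n": 12}
    },
    "eh": {
      "intervention": {"mean_diff": -1.00, "sd_diff": 2.74, "n": 9},
      "control": {"mean_diff": -0.25, "sd_diff": 4.31, "n": 12}
    }
  }
}
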