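{
  "id": "naai1_no_admixture",
  "L": 135,
  "populations": [
    {
      "label": "Mainland",
      "ne": {
        "dist": "uniform",
        "min": 5000,
        "max": 50000
      },
      "sample_size": 40,
      "sampling_age": 0
    },
    {
      "label": "CAA",
      "ne": {
        "dist": "uniform",
        "min": 1000,
        "max": 30000
      },
      "sample_size": 40,
      "sampling_age": 0
    },
    {
      "label": "EastGreenland_BanksMelville",
      "ne": {
        "dist": "uniform",
        "min": 500,
        "max": 10000
      },
      "sample_size": 20,
      "sampling_age": 0
    },
    {
      "label": "WestGreenland",
      "ne": {
        "dist": "uniform",
        "min": 500,
        "max": 10000
      },
      "sample_size": 20,
      "sampling_age": 0
    }
  ],
  "events": [
    {
      "kind": "divergence",
      "name": "wg_split",
      "daughter": "WestGreenland",
      "parent": "Mainland",
      "time": {
        "dist": "uniform",
        "min": 200,
        "max": 2000
      }
    },
    {
      "kind": "divergence",
      "name": "egbm_split",
      "daughter": "EastGreenland_BanksMelville",
      "parent": "CAA",
      "time": {
        "dist": "uniform",
        "min": 200,
        "max": 2000
      }
    },
    {
      "kind": "divergence",
      "name": "caa_split",
      "daughter": "CAA",
      "parent": "Mainland",
      "time": {
        "dist": "uniform",
        "min": 500,
        "max": 3500
      }
    }
  ],
  "mutation": {
    "mu": {
      "dist": "loguniform",
      "min": 1e-06,
      "max": 0.0001
    },
    "kappa": 10,
    "pi": {
      "A": 0.32,
      "C": 0.25,
      "G": 0.13,
      "T": 0.3
    },
    "alpha": 0.5,
    "p_inv": 0.2
  },
  "constraints": []
}
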