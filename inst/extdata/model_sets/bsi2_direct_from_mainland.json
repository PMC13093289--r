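{
  "id": "bsi2_direct_from_mainland",
  "L": 204,
  "populations": [
    {
      "label": "WestRussia",
      "ne": {
        "dist": "uniform",
        "min": 5000,
        "max": 50000
      },
      "sample_size": 40,
      "sampling_age": 0
    },
    {
      "label": "NovayaZemlya",
      "ne": {
        "dist": "uniform",
        "min": 1000,
        "max": 20000
      },
      "sample_size": 30,
      "sampling_age": 0
    },
    {
      "label": "Svalbard",
      "ne": {
        "dist": "uniform",
        "min": 500,
        "max": 10000
      },
      "sample_size": 30,
      "sampling_age": 0
    },
    {
      "label": "FranzJosefLand",
      "ne": {
        "dist": "uniform",
        "min": 500,
        "max": 10000
      },
      "sample_size": 3,
      "sampling_age": 502
    }
  ],
  "events": [
    {
      "kind": "divergence",
      "name": "sv_split",
      "daughter": "Svalbard",
      "parent": "WestRussia",
      "time": {
        "dist": "uniform",
        "min": 550,
        "max": 2500
      }
    },
    {
      "kind": "divergence",
      "name": "fjl_split",
      "daughter": "FranzJosefLand",
      "parent": "NovayaZemlya",
      "time": {
        "dist": "uniform",
        "min": 600,
        "max": 2500
      }
    },
    {
      "kind": "divergence",
      "name": "nz_split",
      "daughter": "NovayaZemlya",
      "parent": "WestRussia",
      "time": {
        "dist": "uniform",
        "min": 700,
        "max": 4000
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
  "constraints": [
    ["t_nz_split", "t_fjl_split"]
  ]
}
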