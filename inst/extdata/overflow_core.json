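{
  "format_version": "1.0",
  "metabolites": [
    {
      "id": "glc_ext",
      "external": true
    },
    {
      "id": "intermediate",
      "external": false
    },
    {
      "id": "ac_ext",
      "external": true
    },
    {
      "id": "precursor",
      "external": false
    }
  ],
  "reactions": [
    {
      "id": "transport",
      "stoichiometry": {
        "glc_ext": -1,
        "intermediate": 1
      },
      "kcat": 10,
      "saturation": {
        "kind": "michaelis_menten",
        "substrate_ids": [
          "glc_ext"
        ],
        "Km": {
          "glc_ext": 1
        }
      },
      "objective": false
    },
    {
      "id": "respiration",
      "stoichiometry": {
        "intermediate": -1,
        "precursor": 1
      },
      "kcat": 2,
      "saturation": {
        "kind": "michaelis_menten",
        "substrate_ids": [
          "intermediate"
        ],
        "Km": {
          "intermediate": 0.5
        }
      },
      "objective": false
    },
    {
      "id": "overflow",
      "stoichiometry": {
        "ac_ext": 1,
        "intermediate": -2,
        "precursor": 1
      },
      "kcat": 6,
      "saturation": {
        "kind": "michaelis_menten",
        "substrate_ids": [
          "intermediate"
        ],
        "Km": {
          "intermediate": 0.5
        }
      },
      "objective": false
    },
    {
      "id": "biomass",
      "stoichiometry": {
        "precursor": -1
      },
      "kcat": 1,
      "saturation": {
        "kind": "constant"
      },
      "objective": true
    }
  ],
  "constraints": [
    {
      "id": "cytosol",
      "weights": {
        "overflow": 1,
        "respiration": 1
      },
      "bound": 1
    },
    {
      "id": "membrane",
      "weights": {
        "transport": 1
      },
      "bound": 0.3
    }
  ]
}
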