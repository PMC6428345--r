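{
  "format_version": "1.0",
  "metabolites": [
    {
      "id": "glc_ext",
      "external": true
    },
    {
      "id": "atp",
      "external": false
    }
  ],
  "reactions": [
    {
      "id": "mixed_acid",
      "stoichiometry": {
        "atp": 3,
        "glc_ext": -1
      },
      "kcat": 2.7,
      "saturation": {
        "kind": "mm_product_inhibition",
        "substrate_ids": [
          "glc_ext"
        ],
        "Km": {
          "glc_ext": 0.4
        },
        "inhibitor_id": "atp",
        "Ki": 0.65
      },
      "objective": false
    },
    {
      "id": "homolactic",
      "stoichiometry": {
        "atp": 2,
        "glc_ext": -1
      },
      "kcat": 2.5,
      "saturation": {
        "kind": "mm_product_inhibition",
        "substrate_ids": [
          "glc_ext"
        ],
        "Km": {
          "glc_ext": 25
        },
        "inhibitor_id": "atp",
        "Ki": 14
      },
      "objective": false
    },
    {
      "id": "biomass",
      "stoichiometry": {
        "atp": -1
      },
      "kcat": 2.7,
      "saturation": {
        "kind": "michaelis_menten",
        "substrate_ids": [
          "atp"
        ],
        "Km": {
          "atp": 0.3
        }
      },
      "objective": true
    }
  ],
  "constraints": [
    {
      "id": "total",
      "weights": {
        "biomass": 1,
        "homolactic": 1,
        "mixed_acid": 1
      },
      "bound": 1
    },
    {
      "id": "uptake",
      "weights": {
        "homolactic": 0.02,
        "mixed_acid": 6.5
      },
      "bound": 0.42
    }
  ]
}
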