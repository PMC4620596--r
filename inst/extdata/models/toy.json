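{
  "schema": "cfba-model/1",
  "id": "toy",
  "flux_time_unit": "second",
  "biomass_start_cap": 1,
  "compounds": [
    {
      "id": "X",
      "kind": "balanced",
      "biomass_weight": 0
    },
    {
      "id": "Y",
      "kind": "dynamic",
      "biomass_weight": 1
    },
    {
      "id": "Z",
      "kind": "dynamic",
      "biomass_weight": 1
    }
  ],
  "reactions": [
    {
      "id": "v1",
      "stoichiometry": {
        "X": 1
      },
      "reversible": false,
      "upper_bound": 0.00277777777777778
    },
    {
      "id": "v2",
      "stoichiometry": {
        "X": -1,
        "Y": 1
      },
      "reversible": false
    },
    {
      "id": "v3",
      "stoichiometry": {
        "X": -1,
        "Z": 1
      },
      "reversible": false
    }
  ],
  "capacity_constraints": [
    {
      "catalyst": "Y",
      "light_modulated": false,
      "terms": [
        {
          "reaction": "v2",
          "inverse_kcat": 64000
        },
        {
          "reaction": "v3",
          "inverse_kcat": 64000
        }
      ]
    }
  ],
  "quota_constraints": [
    {
      "members": "Z",
      "fraction": 0.5,
      "enforce": "start_only"
    }
  ],
  "maintenance_constraints": [],
  "notes": ["Three-reaction illustrative network: X balanced; Y (enzyme) and Z (target) accumulate.", "v1 uptake of X (bounded), v2: X -> Y, v3: X -> Z; both conversions catalyzed by Y", "through one shared capacity row (v2 + v3) * inverse_kcat <= Y.", "Quota: Z >= 0.5 * biomass at simulation start only.", "Parameter defaults (package choices, not printed in the source network):", "kcat(v2) = kcat(v3) = 1/64000 per s (~0.056 per h); v1 upper bound 10 amount/h", "(non-binding); B0 = 1. Chosen so the capacity constraint is tight over the whole", "period, which makes the optimum unique: only the enzyme Y is synthesized at first", "(exponential growth), then a metabolic switch moves the shared capacity to the", "target Z, which accumulates for the rest of the period."]
}
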