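{
  "name": "animal_hierarchy",
  "kind": "structure_config",
  "payload": {
    "F": 5, "n_f": 2, "F1": 2, "F2": 3, "n_f1": 2, "n_f2": 2,
    "n_L1": 2, "n_L2": 2, "n_c": 2, "n_a": 2, "n_g": 2, "epsilon": 0.1
  },
  "comment": "Five binary features; three (limbs, teeth, nails) attach to the general class latent L2, two (head, body) to the specific identity latent L1.",
  "oracle": [
    {
      "quantity": "latent_characteristic_cells",
      "value": 64,
      "provenance": "reference-count",
      "procedure": "single-latent structure: joint feature table 2^5 patterns x 2 latent states"
    },
    {
      "quantity": "hierarchical_characteristic_cells",
      "value": 40,
      "provenance": "reference-count",
      "procedure": "high block (2^3 x 2) x 2 = 32 plus low block 2^2 x 2 = 8"
    },
    {
      "quantity": "hier_threshold",
      "value": 3.5,
      "provenance": "reference-count",
      "procedure": "n_f1^F1 * (n_f2^F2 - 1) / n_f2^F2 = 4 * 7 / 8"
    },
    {
      "quantity": "latent_action_goal_cells",
      "value": 8,
      "provenance": "derived",
      "procedure": "cell enumeration of the goal block: 2 goal states x 2 latent states x 2 actions"
    }
  ]
}
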