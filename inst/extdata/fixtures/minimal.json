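{
  "name": "minimal",
  "kind": "structure_config",
  "payload": {
    "F": 2, "n_f": 2, "F1": 2, "F2": 2, "n_f1": 2, "n_f2": 2,
    "n_L1": 2, "n_L2": 2, "n_c": 2, "n_a": 2, "n_g": 2, "epsilon": 0.1
  },
  "oracle": [
    {
      "quantity": "flat_vs_latent_threshold",
      "value": 2,
      "provenance": "reference-count",
      "procedure": "n_f^F * n_a * n_g / (n_f^F + n_a * n_g) at minimal cardinalities"
    },
    {
      "quantity": "flat_characteristic_cells",
      "value": 16,
      "provenance": "hand-checked",
      "procedure": "goal table cells: 2^2 feature patterns x 2 actions x 2 goal states"
    },
    {
      "quantity": "latent_characteristic_cells",
      "value": 16,
      "provenance": "hand-checked",
      "procedure": "feature table 2^2 x 2 plus goal table 2 x 2 x 2"
    },
    {
      "quantity": "hier_threshold_minimal",
      "value": 3,
      "provenance": "derived",
      "procedure": "n_f1^F1 * (n_f2^F2 - 1) / n_f2^F2 = 4 * 3 / 4 with all quantities minimal"
    },
    {
      "quantity": "context_folded_cells",
      "value": 64,
      "provenance": "reference-count",
      "procedure": "joint feature-and-goal table given folded latent and action"
    },
    {
      "quantity": "explicit_context_cells",
      "value": 24,
      "provenance": "reference-count",
      "procedure": "feature table given latent plus goal table given latent, context, action"
    }
  ]
}
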