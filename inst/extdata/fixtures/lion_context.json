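{
  "name": "lion_context",
  "kind": "world_spec",
  "comment": "Deterministic contextual world. L1: 0 = predator, 1 = prey; C: 0 = wild, 1 = zoo; A: 0 = avoid, 1 = approach. The goal is attained by approaching iff the animal is prey or the context is the zoo, and by avoiding a predator in the wild.",
  "payload": {
    "kind": "contextual",
    "cfg": {
      "F1": 2, "F2": 2, "n_f1": 2, "n_f2": 2, "n_L1": 2, "n_L2": 2,
      "n_c": 2, "n_a": 2, "n_g": 2, "epsilon": 0
    },
    "determinism": {"feature_slack": 0, "goal_slack": 0},
    "patterns": {"low": [3, 0], "high": [3, 4]},
    "goal_rule": {"preferred": [0, 1, 1, 1]},
    "seed": 1
  },
  "oracle": [
    {
      "quantity": "correct_action_predator_wild",
      "value": 0,
      "provenance": "hand-checked",
      "procedure": "rule: avoid a predator in the wild"
    },
    {
      "quantity": "correct_action_predator_zoo",
      "value": 1,
      "provenance": "hand-checked",
      "procedure": "rule: approach at the zoo"
    },
    {
      "quantity": "correct_action_prey_wild",
      "value": 1,
      "provenance": "hand-checked",
      "procedure": "rule: approach prey"
    },
    {
      "quantity": "action_inference_accuracy",
      "value": 1,
      "provenance": "derived",
      "procedure": "exact goal-clamped action posterior on deterministic tables identifies the preferred action for every latent-consistent pattern in both contexts"
    }
  ]
}
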