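{
  "name": "chain3",
  "kind": "model",
  "comment": "Hand-checked three-variable chain X -> Y -> Z with binary states.",
  "payload": {
    "variables": [
      {"name": "X", "role": "feature", "cardinality": 2},
      {"name": "Y", "role": "feature", "cardinality": 2},
      {"name": "Z", "role": "observation", "cardinality": 2}
    ],
    "blocks": [
      {"name": "X", "tag": "prior", "children": ["X"], "parents": [],
       "nrow": 2, "ncol": 1, "index_order": "child-major",
       "table": [0.7, 0.3]},
      {"name": "Y|X", "tag": "chain", "children": ["Y"], "parents": ["X"],
       "nrow": 2, "ncol": 2, "index_order": "child-major",
       "table": [0.8, 0.2, 0.1, 0.9]},
      {"name": "Z|Y", "tag": "chain", "children": ["Z"], "parents": ["Y"],
       "nrow": 2, "ncol": 2, "index_order": "child-major",
       "table": [0.6, 0.4, 0.25, 0.75]}
    ],
    "metadata": {"id": "chain3"}
  },
  "oracle": [
    {
      "quantity": "joint_x1_y1_z0",
      "value": 0.0675,
      "provenance": "hand-checked",
      "procedure": "0.3 * 0.9 * 0.25"
    },
    {
      "quantity": "posterior_x1_given_z1",
      "value": 0.39466421343146274,
      "provenance": "derived",
      "procedure": "full joint enumeration: 0.3*(0.9*0.75+0.1*0.4) / (0.3*(0.9*0.75+0.1*0.4) + 0.7*(0.2*0.75+0.8*0.4)) = 0.2145/0.5435"
    },
    {
      "quantity": "posterior_y1_given_z1",
      "value": 0.56577736890524377,
      "provenance": "derived",
      "procedure": "full joint enumeration: 0.3075/0.5435"
    }
  ]
}
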