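{
  "_comment": "SYNTHETIC example dataset. Mirrors the design of a young oceanic archipelago community (8 independent colonisations, 25 extant species, two mainland-pool classes) but every number is invented for documentation and testing.",
  "island_age": 4,
  "M": 1000,
  "class_fractions": {
    "DF-type": 0.163,
    "non-DF-type": 0.837
  },
  "colonists": [
    {
      "label": "radiation-large",
      "status": 4,
      "colonisation_time": 2.1,
      "branching_times": [1.4, 0.99, 0.83, 0.74, 0.61, 0.55, 0.48, 0.42, 0.37, 0.31, 0.26, 0.2, 0.15, 0.09],
      "n_missing": 0,
      "lineage_class": "DF-type",
      "max_age": false
    },
    {
      "label": "radiation-small",
      "status": 4,
      "colonisation_time": 3.2,
      "branching_times": [1.1, 0.65, 0.35],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": false
    },
    {
      "label": "singleton-old",
      "status": 4,
      "colonisation_time": 3.5,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": false
    },
    {
      "label": "singleton-mid",
      "status": 4,
      "colonisation_time": 1.9,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": false
    },
    {
      "label": "singleton-young",
      "status": 4,
      "colonisation_time": 0.9,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": false
    },
    {
      "label": "upperbound-a",
      "status": 2,
      "colonisation_time": 4,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": true
    },
    {
      "label": "upperbound-b",
      "status": 2,
      "colonisation_time": 2.5,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": true
    },
    {
      "label": "recent-colonist",
      "status": 3,
      "colonisation_time": 0.3,
      "branching_times": [],
      "n_missing": 0,
      "lineage_class": "non-DF-type",
      "max_age": false
    }
  ]
}
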