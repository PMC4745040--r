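{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "island community dataset",
  "description": "One island/archipelago community: island age, mainland pool composition, and one record per independent colonisation. All times are ages in million years (My) before present. The flat TSV export carries the same fields, one colonist per row, with '# key<TAB>value' header lines for island_age, M, class_names and class_fractions, and branching times joined by ';'.",
  "type": "object",
  "required": ["island_age", "M", "class_fractions", "colonists"],
  "properties": {
    "island_age": {"type": "number", "exclusiveMinimum": 0,
                   "description": "age of the island (My)"},
    "M": {"type": "number", "exclusiveMinimum": 0,
          "description": "mainland pool size (species)"},
    "class_fractions": {
      "type": "object",
      "description": "fraction of the mainland pool per lineage class; fractions sum to 1",
      "additionalProperties": {"type": "number", "minimum": 0, "maximum": 1}
    },
    "colonists": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["label", "status"],
        "properties": {
          "label": {"type": "string"},
          "status": {
            "type": "integer", "minimum": 1, "maximum": 5,
            "description": "1 no extant descendants; 2 non-endemic, colonisation time an upper bound; 3 non-endemic, colonisation time known; 4 endemic clade, mainland relative absent; 5 endemic clade plus re-immigrated non-endemic sister"
          },
          "colonisation_time": {
            "type": "number", "exclusiveMinimum": 0,
            "description": "age of colonisation (divergence from the mainland), <= island_age; upper bound when max_age is true; omit for status 1"
          },
          "branching_times": {
            "type": "array", "items": {"type": "number"},
            "description": "ages of in-situ cladogenesis events, all < colonisation_time; statuses 4-5 only"
          },
          "n_missing": {
            "type": "integer", "minimum": 0, "default": 0,
            "description": "extant island species of this colonist absent from the phylogeny"
          },
          "lineage_class": {"type": "string", "default": "all"},
          "max_age": {"type": "boolean", "default": false,
                      "description": "true when colonisation_time is an upper bound (status 2)"}
        }
      }
    }
  }
}
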