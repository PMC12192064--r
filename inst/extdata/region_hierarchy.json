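{
  "subregions": [
    "Parasubiculum",
    "Presubiculum-Head",
    "Subiculum-Head",
    "CA1-Head",
    "CA2/3-Head",
    "CA4-Head",
    "GC-ML-DG-head",
    "molecular_layer_HP-head",
    "HATA",
    "Presubiculum-body",
    "Subiculum-body",
    "CA1-Body",
    "CA2/3-body",
    "CA4-body",
    "GC-ML-DG-body",
    "molecular_layer_HP-body",
    "fimbria",
    "Hippocampal_tail",
    "hippocampal-fissure"
  ],
  "merged_labels": {
    "HEAD": [
      "Parasubiculum",
      "Presubiculum-Head",
      "Subiculum-Head",
      "CA1-Head",
      "CA2/3-Head",
      "CA4-Head",
      "GC-ML-DG-head",
      "molecular_layer_HP-head",
      "HATA"
    ],
    "BODY": [
      "Presubiculum-body",
      "Subiculum-body",
      "CA1-Body",
      "CA2/3-body",
      "CA4-body",
      "GC-ML-DG-body",
      "molecular_layer_HP-body",
      "fimbria"
    ],
    "TAIL": ["Hippocampal_tail"],
    "FISSURE": ["hippocampal-fissure"]
  },
  "combined_labels": {
    "Whole_hippocampal_head": [
      "Parasubiculum",
      "Presubiculum-Head",
      "Subiculum-Head",
      "CA1-Head",
      "CA2/3-Head",
      "CA4-Head",
      "GC-ML-DG-head",
      "molecular_layer_HP-head",
      "HATA"
    ],
    "Whole_hippocampal_body": [
      "Presubiculum-body",
      "Subiculum-body",
      "CA1-Body",
      "CA2/3-body",
      "CA4-body",
      "GC-ML-DG-body",
      "molecular_layer_HP-body",
      "fimbria"
    ],
    "Whole_hippocampus": [
      "Parasubiculum",
      "Presubiculum-Head",
      "Subiculum-Head",
      "CA1-Head",
      "CA2/3-Head",
      "CA4-Head",
      "GC-ML-DG-head",
      "molecular_layer_HP-head",
      "HATA",
      "Presubiculum-body",
      "Subiculum-body",
      "CA1-Body",
      "CA2/3-body",
      "CA4-body",
      "GC-ML-DG-body",
      "molecular_layer_HP-body",
      "fimbria",
      "Hippocampal_tail"
    ]
  },
  "aliases": {
    "Presubiculum": "Presubiculum-Head",
    "CA3-Head": "CA2/3-Head",
    "CA3-Body": "CA2/3-body",
    "HP_tail": "Hippocampal_tail",
    "GC_ML_DG-head": "GC-ML-DG-head",
    "GC_ML_DG-body": "GC-ML-DG-body"
  }
}
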