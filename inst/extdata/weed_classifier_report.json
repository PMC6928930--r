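{
  "classes": ["Cocklebur", "Pigweed", "Ragweed"],
  "precision": {"Cocklebur": 0.94, "Pigweed": 0.94, "Ragweed": 0.96},
  "recall": {"Cocklebur": 1.0, "Pigweed": 0.89, "Ragweed": 0.94},
  "accuracy": {"Cocklebur": 0.99, "Pigweed": 0.99, "Ragweed": 0.99}
}
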