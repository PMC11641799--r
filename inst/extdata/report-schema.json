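{
  "title": "clonemem run report",
  "required": {
    "seed": "number",
    "config": "object",
    "n_genes_tested": "number",
    "deg_counts": "object",
    "pattern_counts": "object",
    "tmg2": "object",
    "tmg3": "object",
    "trait_classes": "object",
    "module_count": "number",
    "module_sizes": "object",
    "module_classes": "object",
    "tmg_fraction_by_class": "object",
    "hub_counts": "object",
    "versions": "object"
  }
}
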