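{
  "out": "haplodeficit_demo",
  "seed": 1,
  "sim": {
    "n_chromosomes": 2,
    "markers_per_chromosome": 512,
    "chromosome_length_bp": 25000000,
    "n_founders": 200,
    "n_generations": 3,
    "matings_per_generation": 500,
    "offspring_per_mating": 1,
    "founder_haplotype_pool": 24,
    "lethal_loci": [
      {
        "chromosome": 1,
        "center_marker": 256,
        "span_markers": 50,
        "target_carrier_frequency": 0.34,
        "penetrance": 1,
        "linked_variant_offset_bp": 1000
      }
    ]
  }
}
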