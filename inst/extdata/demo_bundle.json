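{
  "schema": "thermoprom-bundle-1",
  "upstream_tsv": "demo_bundle_upstream.tsv",
  "downstream_tsv": "demo_bundle_downstream.tsv",
  "spacer_tsv": "demo_bundle_spacers.tsv",
  "dinucleotide_tsv": "demo_bundle_dinucleotides.tsv",
  "mu": -5,
  "clearance_rate": 0,
  "rbs_occlusion_cutoff": 11
}
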