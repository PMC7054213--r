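# Example biological allow-list for signature attribution.
# Each entry names a signature and lists where it may be active; any
# signature without an entry is allowed in every sample. Pass this file
# (or an equivalent list) to allow_mask_from_rules() to build the binary
# signature-by-sample indicator matrix used by attribute_ard() /
# attribute_catalogue().
SynSig2:
  cancer_types: [Lung-AdenoCA, Lung-SCC, Head-SCC]
SynSig4:
  samples: [SP000001]
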