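{
  "deephf_combined_reported": 170659,
  "deephf_crispron_combined_after_filter": 169269,
  "crispron_with_revcomp": 25905,
  "crispron_after_filter": 22055
}
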