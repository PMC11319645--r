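# Frozen encoding constants: letter order and enzyme order are fixed so that
# encodings are reproducible across runs and implementations.

NUCLEOTIDES <- c("A", "C", "G", "T")
ENZYMES <- c("WT", "Esp", "HF")
TOKENS <- c("START", NUCLEOTIDES)  # integer alphabet of size 5 for the RNN
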