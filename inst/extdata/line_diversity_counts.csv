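line,eta,n_sequences
non_rescued,62520.50,24
rescued_bp,41092.00,24
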