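{"Naive": 6, "MPTP": 6, "Acu": 6, "Sham": 6}
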