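central,barrier
C-C,1.40
C-N,1.00
C-O,1.00
C-S,1.00
*,1.00
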