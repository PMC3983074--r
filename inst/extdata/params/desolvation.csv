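iclass,weight
apolar,0.010
acceptor,-0.006
polar.H.carrier,-0.006
donor.H,-0.003
metal,-0.010
other,0.000
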