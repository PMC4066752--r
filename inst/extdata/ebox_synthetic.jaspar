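>EBOX_SYNTH synthetic E-box
A [ 40 3 231 3 3 3 3 160 ]
C [ 20 231 3 231 3 3 3 20 ]
G [ 20 3 3 3 231 3 231 20 ]
T [ 160 3 3 3 3 231 3 40 ]
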