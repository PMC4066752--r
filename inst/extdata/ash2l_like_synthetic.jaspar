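>ASH2L_LIKE_SYNTH synthetic placeholder
A [ 30 30 30 30 30 30 ]
C [ 30 150 30 30 150 30 ]
G [ 150 30 150 150 30 150 ]
T [ 30 30 30 30 30 30 ]
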