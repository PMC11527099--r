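>TOY0001 toy_synthetic
A [ 0.2 0.1 0.4 0.3 ]
C [ 0.3 0.5 0.1 0.2 ]
G [ 0.4 0.3 0.4 0.5 ]
T [ 0.1 0.1 0.1 0.0 ]
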