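>GLI_synthetic GLI-repressor consensus GACCACCCA (synthetic counts)
A [  0 10  0  0 10  0  0  0 10 ]
C [  0  0 10 10  0 10 10 10  0 ]
G [ 10  0  0  0  0  0  0  0  0 ]
T [  0  0  0  0  0  0  0  0  0 ]
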