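feature,value
Monomers,45.16
Dimers,43.29
Trimers,10.54
Tetramers,1.01
Anhydro muropeptide,7.95
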