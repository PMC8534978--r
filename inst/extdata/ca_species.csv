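label,energy,unit,role
CA,-2836114.23,kJ_per_mol,parent
CA-(15)O,-2834498.68,kJ_per_mol,radical
CA-(18)O,-2834506.32,kJ_per_mol,radical
H,-1312.28,kJ_per_mol,hydrogen_atom
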