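label,energy,unit,role
OA,-856.390,hartree,parent
OA-C(8),-855.757199,hartree,radical
OA-C(11),-855.757275,hartree,radical
H,-0.498,hartree,hydrogen_atom
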