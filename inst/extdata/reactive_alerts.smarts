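# Reactive / potentially toxic group alerts (SMARTS<TAB>name).
# Versioned, editable default list.
[CX3](=O)[F,Cl,Br,I]	acyl_halide
[SX4](=O)(=O)[F,Cl,Br,I]	sulfonyl_halide
[CX3H1](=O)[#6]	aldehyde
[CX3]=[CX3][CX3]=[OX1]	michael_acceptor
[CX3]=[CX3][SX4](=O)(=O)	vinyl_sulfone
[OX2r3]1[#6r3][#6r3]1	epoxide
[NX3r3]1[#6r3][#6r3]1	aziridine
[NX2]=[CX2]=[OX1]	isocyanate
[CX3](=O)[OX2][CX3](=O)	anhydride
[CX4;!$(C[F])][Cl,Br,I]	alkyl_halide
[NX2]=[OX1]	nitroso
[OX2][OX2]	peroxide
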