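# Ionizable-group definitions (SMARTS<TAB>name), editable.
# Covers the common acids and bases at physiological pH; phosphonic
# acids are listed for completeness although phosphorus-containing
# molecules are excluded upstream anyway.
[CX3](=O)[OX2H1]	carboxylic_acid
[SX4](=O)(=O)[OX2H1]	sulfonic_acid
[PX4](=O)([OX2H1])[OX2H1]	phosphonic_acid
c1nnn[nH]1	tetrazole
[NX3;H2,H1,H0;+0;!$([NX3][a]);!$([NX3][#6X3]=[O,S,N]);!$([NX3][!#6;!#1])]	aliphatic_amine
[NX3][CX3]=[NX2]	amidine_or_guanidine
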