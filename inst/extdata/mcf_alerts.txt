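# Medicinal-chemistry structural alert list (curated subset).
# One SMARTS per line with an optional tab-separated name. A molecule
# matching any pattern fails the alert filter. This is a compact catalog
# written for this package covering widely agreed reactive or unstable
# motifs; it is not the complete catalogue used by any external benchmark.
[#6]C(=O)[F,Cl,Br,I]	acyl_halide
C(=O)C(=O)	1,2-dicarbonyl
[SX2][Cl,Br,I]	sulfenyl_halide
[N;!R]=[N;!R]	acyclic_azo
N=[N+]=[N-]	azide
[NX2]=O	nitroso
[OX2][OX2]	peroxide
[C;!R](=[C;!R])[C;!R]=[O,N]	acyclic_michael_acceptor
[#6][SX2H]	thiol
C1OC1	epoxide
C1NC1	aziridine
[N+]#[C-]	isocyanide
N=C=O	isocyanate
N=C=S	isothiocyanate
[CX3](=O)OC(=O)	anhydride
[Si]	silicon
[CH]=[CH][CH]=[CH][CH]=[CH]	extended_polyene
[C;R0][C;R0][C;R0][C;R0][C;R0][C;R0][C;R0]	long_aliphatic_chain
[OX2H][OX2H]	geminal_diol
[NX3][NX3]	hydrazine
C=[N+]=[N-]	diazo
[#7][F,Cl,Br,I]	N_halogen
[#8][F,Cl,Br,I]	O_halogen
[P;!$(P(=O)([OX2])([OX2,NX3])[OX2,NX3,#6])]	reactive_phosphorus
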