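# Pan-assay interference (PAINS-like) structural alert list (curated
# subset). One SMARTS per line with an optional tab-separated name.
# A compact catalog written for this package covering prominent classes of
# assay-interfering chemotypes (quinones, catechols, rhodanines,
# ene-rhodanines, azo dyes, Mannich phenols, polyhydroxylated aromatics);
# it is not the complete published PAINS catalogue.
O=C1C=CC(=O)C=C1	para_quinone
O=C1C(=O)C=CC=C1	ortho_quinone
[OH]c1ccc(O)cc1	hydroquinone
[OH]c1cccc(O)c1O	pyrogallol
[OH]c1ccccc1[OH]	catechol
S1C(=O)N(C(=O)C1)	rhodanine_core
S1C(=S)NC(=O)C1	thioxothiazolidinone
C=C1SC(=S)NC1=O	ene_rhodanine
c1ccccc1N=Nc1ccccc1	azo_aromatic
[OH]c1ccccc1C=N	salicylaldimine
C(=O)C=CC(=O)	divinyl_ketone
c1ccc2c(c1)C(=O)c1ccccc1C2=O	anthraquinone
[OH]c1ccc(cc1)C=C	styrenyl_phenol
N=Nc1ccc(O)cc1	azo_phenol
[#6]=[#6]C(=O)c1ccc(O)cc1	enone_phenol
C(=N)N=C	amidine_imine
[OH]c1ccc([OH])c([OH])c1	trihydroxy_aromatic
c1cc(=O)oc2ccccc12	coumarin_isomer
C=C1C(=O)NC(=O)S1	ene_thiazolidinedione
[NX3]c1ccc(N=N)cc1	aminoazo
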