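# Functional group catalog used by functional_groups().
# Compact SMARTS catalog of common medicinal-chemistry functional groups;
# matched with unique-match counting, one multiset entry per occurrence.
name	smarts
carboxylic_acid	[CX3](=O)[OX2H1]
ester	[CX3](=O)[OX2H0][#6]
amide	[CX3](=O)[NX3]
aldehyde	[CX3H1](=O)[#6]
ketone	[#6][CX3](=O)[#6]
primary_amine	[NX3;H2;!$(NC=O)][#6]
secondary_amine	[NX3;H1;!$(NC=O)]([#6])[#6]
tertiary_amine	[NX3;H0;!$(NC=O);!$(N=O)]([#6])([#6])[#6]
hydroxyl	[OX2H][CX4]
phenol	[OX2H][c]
ether	[OD2;!$(OC=O)]([#6])[#6]
nitrile	[NX1]#[CX2]
nitro	[NX3](=O)=O
sulfonamide	[SX4](=O)(=O)[NX3]
sulfone	[SX4](=O)(=O)([#6])[#6]
sulfoxide	[SX3](=O)([#6])[#6]
thioether	[SX2]([#6])[#6]
thiol	[SX2H]
fluoro	[F]
chloro	[Cl]
bromo	[Br]
iodo	[I]
urea	[NX3][CX3](=O)[NX3]
carbamate	[NX3][CX3](=O)[OX2]
guanidine	[NX3][CX3](=[NX2])[NX3]
imine	[CX3]=[NX2]
azo	[NX2]=[NX2]
sulfonic_acid	[SX4](=O)(=O)[OX2H]
phosphate	[PX4](=O)([OX2])([OX2])[OX2]
halomethyl	[CX4]([F,Cl,Br,I])([F,Cl,Br,I])
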