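name	smarts
hydroxyl	[OX2H]
phenol	[OX2H][cX3]
carboxylic_acid	[CX3](=O)[OX2H1]
ester	[CX3](=O)[OX2H0][#6]
ether	[OD2]([#6])[#6]
aldehyde	[CX3H1](=O)[#6]
ketone	[#6][CX3](=O)[#6]
carbonyl	[CX3]=[OX1]
primary_amine	[NX3H2][#6]
secondary_amine	[NX3H1]([#6])[#6]
tertiary_amine	[NX3H0]([#6])([#6])[#6]
amide	[NX3][CX3](=[OX1])
nitrile	[NX1]#[CX2]
nitro	[NX3](~[OX1])~[OX1]
aromatic_6_ring	a1aaaaa1
benzene_ring	c1ccccc1
aromatic_nitrogen	[n]
fluoro	[F]
chloro	[Cl]
bromo	[Br]
iodo	[I]
halogen	[F,Cl,Br,I]
thiol	[SX2H]
sulfide	[SX2]([#6])[#6]
disulfide	[SX2][SX2]
sulfoxide	[SX3]=[OX1]
sulfone	[SX4](=[OX1])=[OX1]
sulfonamide	[SX4](=[OX1])(=[OX1])[NX3]
phosphoryl	[PX4]=[OX1]
alkene	[CX3]=[CX3]
alkyne	[CX2]#[CX2]
methyl	[CX4H3]
methylene	[CX4H2]
quaternary_carbon	[CX4H0]([#6])([#6])([#6])[#6]
imine	[CX3]=[NX2]
urea	[NX3][CX3](=[OX1])[NX3]
carbamate	[NX3][CX3](=[OX1])[OX2]
acyl_halide	[CX3](=[OX1])[F,Cl,Br,I]
anhydride	[CX3](=[OX1])[OX2][CX3](=[OX1])
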