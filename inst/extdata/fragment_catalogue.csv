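name,smarts
azo_any,[NX2]=[NX2]
azo_carbon,[#6][NX2]=[NX2][#6]
azo_diaryl,c[NX2]=[NX2]c
azo_aryl_alkyl,c[NX2]=[NX2][CX4]
n_oxide,[#7+][#8-]
hydroxyl,[OX2H]
alcohol_aliphatic,[CX4][OX2H]
phenol,c[OX2H]
ether,[OD2]([#6])[#6]
aryl_ether,c[OX2][#6]
methoxy,[OX2][CX4H3]
aldehyde,[CX3H1](=O)[#6]
ketone,[#6][CX3](=O)[#6]
carboxylic_acid,[CX3](=O)[OX2H1]
ester,[#6][CX3](=O)[OX2H0][#6]
carboxylate_anion,[CX3](=O)[OX1-]
carbonyl_any,[CX3]=[OX1]
anhydride,[CX3](=O)[OX2][CX3](=O)
amine_primary,[NX3;H2;!$(NC=O)][#6]
amine_secondary,[NX3;H1;!$(NC=O)]([#6])[#6]
amine_tertiary,[NX3;H0;!$(NC=O);!$(N=O)]([#6])([#6])[#6]
aniline_nitrogen,c[NX3]
dimethylamino,[NX3]([CX4H3])[CX4H3]
amide,[NX3][CX3](=[OX1])
amide_primary,[NX3H2][CX3](=[OX1])
urea,[NX3][CX3](=[OX1])[NX3]
carbamate,[NX3][CX3](=[OX1])[OX2]
guanidine,[NX3][CX3](=[NX2])[NX3]
nitrile,[NX1]#[CX2]
nitro,"[$([NX3](=O)=O),$([NX3+](=O)[O-])]"
nitroso,[NX2]=[OX1]
imine,[NX2]=[CX3]
hydrazone,[NX3][NX2]=[CX3]
hydrazine,[NX3][NX3]
hydrazide,[NX3][NX3][CX3]=[OX1]
isocyanate,[NX2]=[CX2]=[OX1]
ammonium_quaternary,[NX4+]
thiol,[SX2H]
sulfide,[#6][SX2][#6]
disulfide,[SX2][SX2]
sulfoxide,[SX3](=[OX1])
sulfone,[SX4](=[OX1])(=[OX1])
sulfonamide,[SX4](=[OX1])(=[OX1])[NX3]
sulfonate,[SX4](=[OX1])(=[OX1])[OX2]
thiocarbonyl,[CX3]=[SX1]
thiocyanate,[SX2][CX2]#[NX1]
fluoro_on_carbon,[#6][F]
chloro_on_carbon,[#6][Cl]
bromo_on_carbon,[#6][Br]
iodo_on_carbon,[#6][I]
fluoro_aromatic,c[F]
chloro_aromatic,c[Cl]
bromo_aromatic,c[Br]
iodo_aromatic,c[I]
trifluoromethyl,[CX4]([F])([F])[F]
halogen_any,"[F,Cl,Br,I]"
benzene_ring,c1ccccc1
aromatic_ring_6,a1aaaaa1
aromatic_ring_5,a1aaaa1
aromatic_carbon,c
aromatic_nitrogen,n
pyridine_type_n,[nX2H0]
pyrrole_type_nh,[nH]
aromatic_oxygen,o
aromatic_sulfur,s
pyridine_ring,c1ccncc1
pyrimidine_ring,c1cncnc1
pyrazole_ring,c1ccnn1
imidazole_ring,c1cncn1
thiazole_ring,c1cscn1
oxazole_ring,c1cocn1
furan_ring,c1ccoc1
thiophene_ring,c1ccsc1
alkene,[CX3]=[CX3]
alkyne,[CX2]#[CX2]
methyl,[CX4H3]
benzylic_ch2,[CX4H2]c
tert_butyl,[CX4]([CX4H3])([CX4H3])[CX4H3]
morpholine_ring,C1COCCN1
piperidine_ring,C1CCNCC1
piperazine_ring,C1CNCCN1
pyrrolidine_ring,C1CCNC1
phosphoryl,[PX4](=[OX1])
boron_any,[#5]
silicon_any,[#14]
acetyl,[CX3](=[OX1])[CX4H3]
vinyl_aromatic,c[CX3]=[CX3]
ortho_fused_aromatic,c12ccccc1cccc2
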