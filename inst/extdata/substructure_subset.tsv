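# Curated substructure-key fingerprint dictionary (SMARTS subset).
# Format: bit<TAB>SMARTS-or-countrule<TAB>description
# Bits 0-3 are the published substructure-key toxicity-alert bits, kept
# under their original identifiers; the rest are generic functional-group
# keys in the same style.
0	[FX1][CX4;!$([H0][Cl,Br,I]);!$([F][C]([F])([F])[F])]([FX1])([FX1])	SubFP294: Trifluoromethyl
1	[FX1][CX4]	SubFP9: Alkylfluoride
2	[nX3H1+0]	SubFP179: Hetero N basic H
3	[!#6;!R0]	SubFP275: Heterocyclic
4	[CX4H3][#6]	Primary carbon (methyl on carbon)
5	[CX3]=[CX3]	Alkene
6	[CX2]#[CX2]	Alkyne
7	[CX4][OX2H]	Alcohol
8	[c][OX2H]	Phenol
9	[CX3](=[OX1])[#6]	Ketone
10	[CX3H1](=[OX1])	Aldehyde
11	[CX3](=[OX1])[OX2H1]	Carboxylic acid
12	[CX3](=[OX1])[OX2][#6]	Ester
13	[CX3](=[OX1])[NX3]	Amide
14	[NX3;H2][CX4]	Primary aliphatic amine
15	[NX3;H1]([CX4])[CX4]	Secondary aliphatic amine
16	[NX3]([CX4])([CX4])[CX4]	Tertiary aliphatic amine
17	[NX3;H2][c]	Primary aromatic amine
18	[NX3;H1]([c])[#6]	Secondary arylamine
19	[CX2]#[NX1]	Nitrile
20	[NX3](=[OX1])([OX1-,OX1])	Nitro group
21	[NX2]=[NX2]	Azo group
22	[CX3]=[NX2]	Imine (C=N)
23	[NX2]=[OX1]	Nitroso
24	[OX2]([#6])[#6]	Ether
25	[SX2H]	Thiol
26	[SX2]([#6])[#6]	Thioether
27	[SX4](=[OX1])(=[OX1])	Sulfonyl
28	[SX4](=[OX1])(=[OX1])[NX3]	Sulfonamide
29	[PX4](=[OX1])	Phosphoryl
30	[PX4](=[OX1])([OX2])([OX2])	Phosphate ester
31	[CX4][Cl]	Alkylchloride
32	[CX4][Br]	Alkylbromide
33	[CX4][I]	Alkyliodide
34	[c][F]	Arylfluoride
35	[c][Cl]	Arylchloride
36	[c][Br]	Arylbromide
37	[c][I]	Aryliodide
38	c1ccccc1	Benzene ring
39	[nX2]	Pyridine-type aromatic nitrogen
40	[o]	Aromatic oxygen
41	[sX2]	Aromatic sulfur
42	[R2]	Fused-ring atom
43	[CX4R]	Saturated ring carbon
44	[OX2r5,OX2r6]	Cyclic ether (5/6-ring oxygen)
45	[NX3R]	Aliphatic ring nitrogen
46	[CX3](=[OX1])[NX3][CX3](=[OX1])	Imide
47	[NX3][CX3](=[OX1])[NX3]	Urea
48	[NX3][CX3](=[OX1])[OX2]	Carbamate
49	[NX3][CX3](=[NX2])[NX3]	Guanidine
50	[CX3](=[SX1])	Thiocarbonyl
51	[SX2][SX2]	Disulfide
52	[OX2][OX2]	Peroxide
53	[NX3][NX3]	Hydrazine-type N-N
54	[CX3]=[CX3][CX3]=[OX1]	Michael acceptor (enone)
55	[OX1]=[CX3][CX3]=[OX1]	1,2-Dicarbonyl
56	[CX4]([OX2])[OX2]	Acetal-type carbon
57	[c][CX3](=[OX1])	Aryl carbonyl
58	[c][NX3](=[OX1])([OX1-,OX1])	Aromatic nitro
59	[C;!R][N;!R][C;!R]	Acyclic C-N-C
60	[CX4H2]([F,Cl,Br,I])[F,Cl,Br,I]	Geminal dihalide
61	[CX4]([F,Cl,Br,I])([F,Cl,Br,I])[F,Cl,Br,I]	Trihalomethyl
62	[#7;+]	Charged nitrogen (cationic)
63	[#8;-]	Anionic oxygen
64	[Si]	Silicon
65	[Se]	Selenium
66	[As]	Arsenic
67	[#6]=[#6][#6]#[#7]	Acrylonitrile-type
68	[NX2]=[CX3][NX3]	Amidine
69	[OX2H][CX4][CX4][NX3]	Beta-aminoalcohol
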