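# Curated PubChem-style fingerprint dictionary subset.
# Format: bit<TAB>SMARTS-or-countrule<TAB>description
# Count rules have the form El>=n (element symbol, minimum count) and
# mirror the hierarchic element-count section of the full 881-bit
# dictionary; bits carrying the published alert identifiers keep them.
# The full official dictionary can be supplied as a user file in the same
# format.
0	N>=1	PubchemFP14: Counts of N >= 1
1	N>=2	PubchemFP15: Counts of N >= 2
2	N>=4	Counts of N >= 4
3	O>=1	Counts of O >= 1
4	O>=2	Counts of O >= 2
5	O>=4	Counts of O >= 4
6	F>=1	Counts of F >= 1
7	F>=2	Counts of F >= 2
8	Cl>=1	Counts of Cl >= 1
9	Cl>=2	Counts of Cl >= 2
10	Br>=1	Counts of Br >= 1
11	I>=1	Counts of I >= 1
12	S>=1	Counts of S >= 1
13	P>=1	Counts of P >= 1
14	C>=2	Counts of C >= 2
15	C>=8	Counts of C >= 8
16	C>=16	Counts of C >= 16
17	[#7;H1]([#6;a])[#6;a]	PubchemFP400: Aromatic C-NH-C bond
18	[#6]([#6])(:[#7]):[#7]	PubchemFP359: C(~C)(:N)(:N) aromatic 1,3-diaza neighbor
19	[#7]c1c([#7])cccc1	PubchemFP770: Ortho aryl nitrogen Nc1c(N)cccc1
20	[#7]C1C([#7])CCCC1	PubchemFP833: Ortho alicyclic nitrogen NC1C(N)CCCC1
21	c:c:[nH]	PubchemFP527: C:C:N-H aromatic neighborhood
22	[#6](-[#6])=[#7]	PubchemFP442: C(-C)(=N) N-alkylimino neighborhood
23	[#6]=[#7]	PubchemFP418: C=N carbon-nitrogen double bond
24	[#6]#[#7]	C#N triple bond
25	[#6]=[#8]	C=O double bond
26	[#6]-[#7]	C-N single bond
27	[#6]-[#8]	C-O single bond
28	[#6]-[#16]	C-S single bond
29	[#7]-[#8]	N-O single bond
30	[#15]=[#8]	P=O double bond
31	[#16]=[#8]	S=O double bond
32	c1ccccc1	Unsubstituted benzene ring
33	[cR1]1[cR1][cR1][cR1][cR1][nR1]1	Six-membered aromatic ring with one N
34	[R]	Any ring atom
35	[R2]	Fused ring atom
36	[a!c]	Aromatic heteroatom
37	[CX4H2]	Methylene carbon
38	[CX4H1]	Methine carbon
39	[CX4H0]	Quaternary-substituted carbon
40	[#8;H1]	Hydroxyl-type oxygen
41	[#7;H2]	Primary amine nitrogen
42	[#7;H1]	Secondary amine-type nitrogen
43	[F,Cl,Br,I]	Any halogen
44	[#6](=[#8])[#8]	Carboxyl neighborhood C(=O)O
45	[#6](=[#8])[#7]	Amide neighborhood C(=O)N
46	[#7](=[#8])[#8]	Nitro-type neighborhood N(=O)O
47	[#6]1[#6][#6][#6][#6][#6]1	Saturated six-ring of carbons
48	[#6]1[#6][#6][#6][#6]1	Saturated five-ring of carbons
49	[#7]1[#6][#6][#6][#6][#6]1	Saturated six-ring with one N
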