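# Per-residue property scale registry. One row per scale; columns A..Y are the
# 20 standard residues in one-letter alphabetical order. Rows without values are
# placeholders for scales whose numeric tables live in external compilations;
# only rows with all 20 values filled are usable for computation.
# mant_hydrophobicity: published RPLC retention-time coefficients.
# isoelectric_point: textbook free-amino-acid pI values (externally sourced).
# longrange_energy_synthetic: SYNTHETIC stand-in for the long-range non-bonded
#   energy scale (the published per-residue values are not bundled); ordering
#   follows residue burial tendency, magnitudes are arbitrary units in [0,1].
scale	description	units	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
mant_hydrophobicity	RPLC retention-time hydrophobicity coefficient h	retention units	13.26	26.84	8.15	11.12	90.17	3.80	4.14	69.53	2.92	73.84	51.64	1.00	27.54	6.00	10.24	3.53	11.64	44.60	100.00	47.49
isoelectric_point	free amino acid isoelectric point pI	pH units	6.00	5.07	2.77	3.22	5.48	5.97	7.59	6.02	9.74	5.98	5.74	5.41	6.30	5.65	10.76	5.68	5.60	5.96	5.89	5.66
longrange_energy_synthetic	synthetic stand-in for long-range non-bonded contact energy	arbitrary	0.48	0.88	0.30	0.27	0.91	0.42	0.54	0.95	0.20	0.92	0.81	0.33	0.36	0.31	0.29	0.41	0.48	0.89	0.85	0.72
K0	compressibility	-
Ht	thermodynamic transfer hydrophobicity	-
Hp	surrounding hydrophobicity	-
P	polarity	-
pHi	isoelectric point (compilation entry)	-
pK	side-chain pK'	-
Mw	molecular weight	Da
Bl	bulkiness	-
Rf	chromatographic Rf	-
Mu	refractive index	-
Hnc	normalized consensus hydrophobicity	-
Esm	short+medium range non-bonded energy	-
El	long-range non-bonded energy	-
Et	total non-bonded energy	-
Pa	alpha-helix propensity	-
Pb	beta-strand propensity	-
Pt	turn propensity	-
Pc	coil propensity	-
Ca	helical contact area	-
F	mean rms fluctuation	-
Br	buriedness	-
Ra	solvent-accessible reduction ratio	-
Ns	average number of surrounding residues	-
aN	power to be at N-terminal of helix	-
aC	power to be at C-terminal of helix	-
am	power to be in middle of helix	-
V0	partial specific volume	-
Nm	average medium-range contacts	-
Nl	average long-range contacts	-
Hgm	combined surrounding hydrophobicity	-
ASAD	solvent-accessible surface area, denatured	A^2
ASAN	solvent-accessible surface area, native	A^2
dASA	solvent-accessible surface area change on folding	A^2
dGh	Gibbs free energy change of hydration on folding	kcal/mol
GhD	Gibbs free energy of hydration, denatured	kcal/mol
GhN	Gibbs free energy of hydration, native	kcal/mol
dHh	enthalpy change of hydration	kcal/mol
TdSh	entropic hydration term -T dS_h	kcal/mol
dCph	heat capacity change of hydration	cal/(mol K)
dGc	Gibbs free energy change, chain	kcal/mol
dHc	enthalpy change, chain	kcal/mol
TdSc	entropic chain term -T dS_c	kcal/mol
dG	unfolding Gibbs free energy change	kcal/mol
dH	unfolding enthalpy change	kcal/mol
TdS	unfolding entropic term -T dS	kcal/mol
v	partial volume	-
s	shape parameter	-
f	flexibility parameter	-
Pphipsi	backbone dihedral propensity	-
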