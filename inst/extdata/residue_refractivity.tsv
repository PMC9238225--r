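# Per-residue data for composition-based protein refractive index increment
# (dn/dc) estimation at 589 nm, 25 C, following the computational approach of
# Zhao, Brown & Schuck (2011) Biophys J 100:2309-2317, built on amino-acid
# refractivities of McMeekin, Wilensky & Groves (1964) and Cohn-Edsall residue
# partial specific volumes.
# mass_residue: average residue mass (free amino acid minus one water), g/mol.
# vbar: residue partial specific volume, mL/g.
# dndc: residue-level refractive index increment at 589 nm / 25 C in water, mL/g.
residue	name	mass_residue	vbar	dndc
A	alanine	71.0788	0.74	0.167
R	arginine	156.1875	0.70	0.206
N	asparagine	114.1038	0.62	0.192
D	aspartate	115.0886	0.60	0.197
C	cysteine	103.1388	0.63	0.206
E	glutamate	129.1155	0.66	0.183
Q	glutamine	128.1307	0.67	0.186
G	glycine	57.0519	0.64	0.175
H	histidine	137.1411	0.67	0.219
I	isoleucine	113.1594	0.90	0.179
L	leucine	113.1594	0.90	0.173
K	lysine	128.1741	0.82	0.181
M	methionine	131.1926	0.75	0.204
F	phenylalanine	147.1766	0.77	0.244
P	proline	97.1167	0.76	0.165
S	serine	87.0782	0.63	0.170
T	threonine	101.1051	0.70	0.172
W	tryptophan	186.2132	0.74	0.277
Y	tyrosine	163.1760	0.71	0.240
V	valine	99.1326	0.86	0.172
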