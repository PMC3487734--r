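# Random-coil HA chemical shifts (ppm) by residue type, from the standard
# random-coil compilation used for secondary-shift analysis of peptides.
# Editable: replace via random_coil_shifts(path = ...).
resname	code	shift_ppm
ALA	A	4.32
ARG	R	4.34
ASN	N	4.74
ASP	D	4.64
CYS	C	4.55
GLN	Q	4.34
GLU	E	4.35
GLY	G	3.96
HIS	H	4.73
ILE	I	4.17
LEU	L	4.34
LYS	K	4.32
MET	M	4.48
PHE	F	4.62
PRO	P	4.42
SER	S	4.47
THR	T	4.35
TRP	W	4.66
TYR	Y	4.55
VAL	V	4.12
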