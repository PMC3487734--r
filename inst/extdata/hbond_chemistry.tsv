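# Donor/acceptor chemistry for protein hydrogen-bond detection.
# resname "*" applies to every amino-acid residue (backbone).
# role: donor, acceptor or both. hydrogens: comma-separated names of the
# hydrogens attached to a donor; "auto" means reconstruct the backbone amide
# hydrogen geometrically when it is absent from the structure.
resname	atom	role	hydrogens
*	N	donor	H,HN,auto
*	O	acceptor
*	OXT	acceptor
SER	OG	both	HG,HG1
THR	OG1	both	HG1
TYR	OH	both	HH
CYS	SG	both	HG,HG1
ASN	OD1	acceptor
ASN	ND2	donor	HD21,HD22
GLN	OE1	acceptor
GLN	NE2	donor	HE21,HE22
HIS	ND1	both	HD1
HIS	NE2	both	HE2
TRP	NE1	donor	HE1
ARG	NE	donor	HE
ARG	NH1	donor	HH11,HH12
ARG	NH2	donor	HH21,HH22
LYS	NZ	donor	HZ1,HZ2,HZ3
ASP	OD1	acceptor
ASP	OD2	acceptor
GLU	OE1	acceptor
GLU	OE2	acceptor
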