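residue_name	atom_name	charge_e
*	N	-0.31
*	H	0.31
*	CA	0.00
*	C	0.45
*	O	-0.45
*	OXT	-0.635
ASP	CB	0.00
ASP	CG	0.27
ASP	OD1	-0.635
ASP	OD2	-0.635
GLU	CG	0.00
GLU	CD	0.27
GLU	OE1	-0.635
GLU	OE2	-0.635
LYS	CE	0.127
LYS	NZ	0.129
LYS	HZ1	0.248
LYS	HZ2	0.248
LYS	HZ3	0.248
ARG	CD	0.09
ARG	NE	-0.11
ARG	HE	0.24
ARG	CZ	0.34
ARG	NH1	-0.26
ARG	NH2	-0.26
ARG	HH11	0.24
ARG	HH12	0.24
ARG	HH21	0.24
ARG	HH22	0.24
HIS	CB	0.00
HIS	CG	0.00
HIS	ND1	-0.05
HIS	CD2	0.13
HIS	CE1	0.26
HIS	NE2	-0.58
HIS	HD1	0.30
HIS	HE2	0.30
SER	CB	0.15
SER	OG	-0.548
SER	HG	0.398
THR	CB	0.15
THR	OG1	-0.548
THR	HG1	0.398
TYR	CZ	0.15
TYR	OH	-0.548
TYR	HH	0.398
CYS	CB	0.10
CYS	SG	-0.10
MET	CG	0.10
MET	SD	-0.20
MET	CE	0.10
ASN	CG	0.29
ASN	OD1	-0.45
ASN	ND2	-0.72
ASN	HD21	0.44
ASN	HD22	0.44
GLN	CD	0.29
GLN	OE1	-0.45
GLN	NE2	-0.72
GLN	HE21	0.44
GLN	HE22	0.44
TRP	NE1	-0.10
TRP	HE1	0.10
HEM	FE	0.40
HEM	NA	-0.10
HEM	NB	-0.10
HEM	NC	-0.10
HEM	ND	-0.10
HEC	FE	0.40
HEC	NA	-0.10
HEC	NB	-0.10
HEC	NC	-0.10
HEC	ND	-0.10
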