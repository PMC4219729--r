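res_name	atom_name	charge_e	radius_A	lj_eps_kcal	lj_rmin_half_A
GLY	N	-0.4	1.55	0.17	1.85
GLY	CA	0.35	1.7	0.1	2
GLY	C	0.55	1.7	0.1	2
GLY	O	-0.5	1.52	0.21	1.7
ALA	N	-0.4	1.55	0.17	1.85
ALA	CA	0.35	1.7	0.1	2
ALA	C	0.55	1.7	0.1	2
ALA	O	-0.5	1.52	0.21	1.7
ALA	CB	0	1.7	0.1	2
VAL	N	-0.4	1.55	0.17	1.85
VAL	CA	0.35	1.7	0.1	2
VAL	C	0.55	1.7	0.1	2
VAL	O	-0.5	1.52	0.21	1.7
VAL	CB	0	1.7	0.1	2
VAL	CG1	0	1.7	0.1	2
VAL	CG2	0	1.7	0.1	2
LEU	N	-0.4	1.55	0.17	1.85
LEU	CA	0.35	1.7	0.1	2
LEU	C	0.55	1.7	0.1	2
LEU	O	-0.5	1.52	0.21	1.7
LEU	CB	0	1.7	0.1	2
LEU	CG	0	1.7	0.1	2
LEU	CD1	0	1.7	0.1	2
LEU	CD2	0	1.7	0.1	2
ILE	N	-0.4	1.55	0.17	1.85
ILE	CA	0.35	1.7	0.1	2
ILE	C	0.55	1.7	0.1	2
ILE	O	-0.5	1.52	0.21	1.7
ILE	CB	0	1.7	0.1	2
ILE	CG1	0	1.7	0.1	2
ILE	CG2	0	1.7	0.1	2
ILE	CD1	0	1.7	0.1	2
PRO	N	-0.4	1.55	0.17	1.85
PRO	CA	0.35	1.7	0.1	2
PRO	C	0.55	1.7	0.1	2
PRO	O	-0.5	1.52	0.21	1.7
PRO	CB	0	1.7	0.1	2
PRO	CG	0	1.7	0.1	2
PRO	CD	0	1.7	0.1	2
PHE	N	-0.4	1.55	0.17	1.85
PHE	CA	0.35	1.7	0.1	2
PHE	C	0.55	1.7	0.1	2
PHE	O	-0.5	1.52	0.21	1.7
PHE	CB	0	1.7	0.1	2
PHE	CG	0	1.7	0.1	2
PHE	CD1	0	1.7	0.1	2
PHE	CD2	0	1.7	0.1	2
PHE	CE1	0	1.7	0.1	2
PHE	CE2	0	1.7	0.1	2
PHE	CZ	0	1.7	0.1	2
TYR	N	-0.4	1.55	0.17	1.85
TYR	CA	0.35	1.7	0.1	2
TYR	C	0.55	1.7	0.1	2
TYR	O	-0.5	1.52	0.21	1.7
TYR	CB	0	1.7	0.1	2
TYR	CG	0	1.7	0.1	2
TYR	CD1	0	1.7	0.1	2
TYR	CD2	0	1.7	0.1	2
TYR	CE1	0	1.7	0.1	2
TYR	CE2	0	1.7	0.1	2
TYR	CZ	0.25	1.7	0.1	2
TYR	OH	-0.25	1.52	0.21	1.7
TRP	N	-0.4	1.55	0.17	1.85
TRP	CA	0.35	1.7	0.1	2
TRP	C	0.55	1.7	0.1	2
TRP	O	-0.5	1.52	0.21	1.7
TRP	CB	0	1.7	0.1	2
TRP	CG	0	1.7	0.1	2
TRP	CD1	0.1	1.7	0.1	2
TRP	CD2	0	1.7	0.1	2
TRP	NE1	-0.3	1.55	0.17	1.85
TRP	CE2	0.2	1.7	0.1	2
TRP	CE3	0	1.7	0.1	2
TRP	CZ2	0	1.7	0.1	2
TRP	CZ3	0	1.7	0.1	2
TRP	CH2	0	1.7	0.1	2
SER	N	-0.4	1.55	0.17	1.85
SER	CA	0.35	1.7	0.1	2
SER	C	0.55	1.7	0.1	2
SER	O	-0.5	1.52	0.21	1.7
SER	CB	0.25	1.7	0.1	2
SER	OG	-0.25	1.52	0.21	1.7
THR	N	-0.4	1.55	0.17	1.85
THR	CA	0.35	1.7	0.1	2
THR	C	0.55	1.7	0.1	2
THR	O	-0.5	1.52	0.21	1.7
THR	CB	0.25	1.7	0.1	2
THR	OG1	-0.25	1.52	0.21	1.7
THR	CG2	0	1.7	0.1	2
CYS	N	-0.4	1.55	0.17	1.85
CYS	CA	0.35	1.7	0.1	2
CYS	C	0.55	1.7	0.1	2
CYS	O	-0.5	1.52	0.21	1.7
CYS	CB	0.1	1.7	0.1	2
CYS	SG	-0.1	1.8	0.45	2
MET	N	-0.4	1.55	0.17	1.85
MET	CA	0.35	1.7	0.1	2
MET	C	0.55	1.7	0.1	2
MET	O	-0.5	1.52	0.21	1.7
MET	CB	0	1.7	0.1	2
MET	CG	0.06	1.7	0.1	2
MET	SD	-0.12	1.8	0.45	2
MET	CE	0.06	1.7	0.1	2
ASN	N	-0.4	1.55	0.17	1.85
ASN	CA	0.35	1.7	0.1	2
ASN	C	0.55	1.7	0.1	2
ASN	O	-0.5	1.52	0.21	1.7
ASN	CB	0.3	1.7	0.1	2
ASN	CG	0.55	1.7	0.1	2
ASN	OD1	-0.55	1.52	0.21	1.7
ASN	ND2	-0.3	1.55	0.17	1.85
GLN	N	-0.4	1.55	0.17	1.85
GLN	CA	0.35	1.7	0.1	2
GLN	C	0.55	1.7	0.1	2
GLN	O	-0.5	1.52	0.21	1.7
GLN	CB	0	1.7	0.1	2
GLN	CG	0.3	1.7	0.1	2
GLN	CD	0.55	1.7	0.1	2
GLN	OE1	-0.55	1.52	0.21	1.7
GLN	NE2	-0.3	1.55	0.17	1.85
ASP	N	-0.4	1.55	0.17	1.85
ASP	CA	0.35	1.7	0.1	2
ASP	C	0.55	1.7	0.1	2
ASP	O	-0.5	1.52	0.21	1.7
ASP	CB	-0.1	1.7	0.1	2
ASP	CG	0.55	1.7	0.1	2
ASP	OD1	-0.725	1.52	0.21	1.7
ASP	OD2	-0.725	1.52	0.21	1.7
GLU	N	-0.4	1.55	0.17	1.85
GLU	CA	0.35	1.7	0.1	2
GLU	C	0.55	1.7	0.1	2
GLU	O	-0.5	1.52	0.21	1.7
GLU	CB	0	1.7	0.1	2
GLU	CG	-0.1	1.7	0.1	2
GLU	CD	0.55	1.7	0.1	2
GLU	OE1	-0.725	1.52	0.21	1.7
GLU	OE2	-0.725	1.52	0.21	1.7
LYS	N	-0.4	1.55	0.17	1.85
LYS	CA	0.35	1.7	0.1	2
LYS	C	0.55	1.7	0.1	2
LYS	O	-0.5	1.52	0.21	1.7
LYS	CB	0	1.7	0.1	2
LYS	CG	0	1.7	0.1	2
LYS	CD	0.1	1.7	0.1	2
LYS	CE	0.25	1.7	0.1	2
LYS	NZ	0.65	1.55	0.17	1.85
ARG	N	-0.4	1.55	0.17	1.85
ARG	CA	0.35	1.7	0.1	2
ARG	C	0.55	1.7	0.1	2
ARG	O	-0.5	1.52	0.21	1.7
ARG	CB	0	1.7	0.1	2
ARG	CG	0	1.7	0.1	2
ARG	CD	0.1	1.7	0.1	2
ARG	NE	-0.4	1.55	0.17	1.85
ARG	CZ	0.7	1.7	0.1	2
ARG	NH1	0.3	1.55	0.17	1.85
ARG	NH2	0.3	1.55	0.17	1.85
HIS	N	-0.4	1.55	0.17	1.85
HIS	CA	0.35	1.7	0.1	2
HIS	C	0.55	1.7	0.1	2
HIS	O	-0.5	1.52	0.21	1.7
HIS	CB	0	1.7	0.1	2
HIS	CG	0.1	1.7	0.1	2
HIS	ND1	-0.4	1.55	0.17	1.85
HIS	CD2	0.1	1.7	0.1	2
HIS	CE1	0.3	1.7	0.1	2
HIS	NE2	-0.1	1.55	0.17	1.85
BE	BE	2	1.53	0.01	0.75
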