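residue	atom1	atom2
ALA	N	CA
ALA	N	H
ALA	CA	C
ALA	CA	CB
ALA	CA	HA
ALA	C	O
ALA	CB	HB1
ALA	CB	HB2
ALA	CB	HB3
ARG	N	CA
ARG	N	H
ARG	CA	C
ARG	CA	CB
ARG	CA	HA
ARG	C	O
ARG	CB	CG
ARG	CB	HB2
ARG	CB	HB3
ARG	CG	CD
ARG	CG	HG2
ARG	CG	HG3
ARG	CD	NE
ARG	CD	HD2
ARG	CD	HD3
ARG	NE	CZ
ARG	NE	HE
ARG	CZ	NH1
ARG	CZ	NH2
ARG	NH1	HH11
ARG	NH1	HH12
ARG	NH2	HH21
ARG	NH2	HH22
ASN	N	CA
ASN	N	H
ASN	CA	C
ASN	CA	CB
ASN	CA	HA
ASN	C	O
ASN	CB	CG
ASN	CB	HB2
ASN	CB	HB3
ASN	CG	OD1
ASN	CG	ND2
ASN	ND2	HD21
ASN	ND2	HD22
ASP	N	CA
ASP	N	H
ASP	CA	C
ASP	CA	CB
ASP	CA	HA
ASP	C	O
ASP	CB	CG
ASP	CB	HB2
ASP	CB	HB3
ASP	CG	OD1
ASP	CG	OD2
CYS	N	CA
CYS	N	H
CYS	CA	C
CYS	CA	CB
CYS	CA	HA
CYS	C	O
CYS	CB	SG
CYS	CB	HB2
CYS	CB	HB3
CYS	SG	HG
GLN	N	CA
GLN	N	H
GLN	CA	C
GLN	CA	CB
GLN	CA	HA
GLN	C	O
GLN	CB	CG
GLN	CB	HB2
GLN	CB	HB3
GLN	CG	CD
GLN	CG	HG2
GLN	CG	HG3
GLN	CD	OE1
GLN	CD	NE2
GLN	NE2	HE21
GLN	NE2	HE22
GLU	N	CA
GLU	N	H
GLU	CA	C
GLU	CA	CB
GLU	CA	HA
GLU	C	O
GLU	CB	CG
GLU	CB	HB2
GLU	CB	HB3
GLU	CG	CD
GLU	CG	HG2
GLU	CG	HG3
GLU	CD	OE1
GLU	CD	OE2
GLY	N	CA
GLY	N	H
GLY	CA	C
GLY	CA	HA2
GLY	CA	HA3
GLY	C	O
HIS	N	CA
HIS	N	H
HIS	CA	C
HIS	CA	CB
HIS	CA	HA
HIS	C	O
HIS	CB	CG
HIS	CB	HB2
HIS	CB	HB3
HIS	CG	ND1
HIS	CG	CD2
HIS	ND1	CE1
HIS	CD2	NE2
HIS	CD2	HD2
HIS	CE1	NE2
HIS	CE1	HE1
HIS	NE2	HE2
ILE	N	CA
ILE	N	H
ILE	CA	C
ILE	CA	CB
ILE	CA	HA
ILE	C	O
ILE	CB	CG1
ILE	CB	CG2
ILE	CB	HB
ILE	CG1	CD1
ILE	CG1	HG12
ILE	CG1	HG13
ILE	CG2	HG21
ILE	CG2	HG22
ILE	CG2	HG23
ILE	CD1	HD11
ILE	CD1	HD12
ILE	CD1	HD13
LEU	N	CA
LEU	N	H
LEU	CA	C
LEU	CA	CB
LEU	CA	HA
LEU	C	O
LEU	CB	CG
LEU	CB	HB2
LEU	CB	HB3
LEU	CG	CD1
LEU	CG	CD2
LEU	CG	HG
LEU	CD1	HD11
LEU	CD1	HD12
LEU	CD1	HD13
LEU	CD2	HD21
LEU	CD2	HD22
LEU	CD2	HD23
LYS	N	CA
LYS	N	H
LYS	CA	C
LYS	CA	CB
LYS	CA	HA
LYS	C	O
LYS	CB	CG
LYS	CB	HB2
LYS	CB	HB3
LYS	CG	CD
LYS	CG	HG2
LYS	CG	HG3
LYS	CD	CE
LYS	CD	HD2
LYS	CD	HD3
LYS	CE	NZ
LYS	CE	HE2
LYS	CE	HE3
LYS	NZ	HZ1
LYS	NZ	HZ2
LYS	NZ	HZ3
MET	N	CA
MET	N	H
MET	CA	C
MET	CA	CB
MET	CA	HA
MET	C	O
MET	CB	CG
MET	CB	HB2
MET	CB	HB3
MET	CG	SD
MET	CG	HG2
MET	CG	HG3
MET	SD	CE
MET	CE	HE1
MET	CE	HE2
MET	CE	HE3
PHE	N	CA
PHE	N	H
PHE	CA	C
PHE	CA	CB
PHE	CA	HA
PHE	C	O
PHE	CB	CG
PHE	CB	HB2
PHE	CB	HB3
PHE	CG	CD1
PHE	CG	CD2
PHE	CD1	CE1
PHE	CD1	HD1
PHE	CD2	CE2
PHE	CD2	HD2
PHE	CE1	CZ
PHE	CE1	HE1
PHE	CE2	CZ
PHE	CE2	HE2
PHE	CZ	HZ
PRO	N	CA
PRO	N	CD
PRO	CA	C
PRO	CA	CB
PRO	CA	HA
PRO	C	O
PRO	CB	CG
PRO	CB	HB2
PRO	CB	HB3
PRO	CG	CD
PRO	CG	HG2
PRO	CG	HG3
PRO	CD	HD2
PRO	CD	HD3
SER	N	CA
SER	N	H
SER	CA	C
SER	CA	CB
SER	CA	HA
SER	C	O
SER	CB	OG
SER	CB	HB2
SER	CB	HB3
SER	OG	HG
THR	N	CA
THR	N	H
THR	CA	C
THR	CA	CB
THR	CA	HA
THR	C	O
THR	CB	OG1
THR	CB	CG2
THR	CB	HB
THR	OG1	HG1
THR	CG2	HG21
THR	CG2	HG22
THR	CG2	HG23
TRP	N	CA
TRP	N	H
TRP	CA	C
TRP	CA	CB
TRP	CA	HA
TRP	C	O
TRP	CB	CG
TRP	CB	HB2
TRP	CB	HB3
TRP	CG	CD1
TRP	CG	CD2
TRP	CD1	NE1
TRP	CD1	HD1
TRP	CD2	CE2
TRP	CD2	CE3
TRP	NE1	CE2
TRP	NE1	HE1
TRP	CE2	CZ2
TRP	CE3	CZ3
TRP	CE3	HE3
TRP	CZ2	CH2
TRP	CZ2	HZ2
TRP	CZ3	CH2
TRP	CZ3	HZ3
TRP	CH2	HH2
TYR	N	CA
TYR	N	H
TYR	CA	C
TYR	CA	CB
TYR	CA	HA
TYR	C	O
TYR	CB	CG
TYR	CB	HB2
TYR	CB	HB3
TYR	CG	CD1
TYR	CG	CD2
TYR	CD1	CE1
TYR	CD1	HD1
TYR	CD2	CE2
TYR	CD2	HD2
TYR	CE1	CZ
TYR	CE1	HE1
TYR	CE2	CZ
TYR	CE2	HE2
TYR	CZ	OH
TYR	OH	HH
VAL	N	CA
VAL	N	H
VAL	CA	C
VAL	CA	CB
VAL	CA	HA
VAL	C	O
VAL	CB	CG1
VAL	CB	CG2
VAL	CB	HB
VAL	CG1	HG11
VAL	CG1	HG12
VAL	CG1	HG13
VAL	CG2	HG21
VAL	CG2	HG22
VAL	CG2	HG23
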