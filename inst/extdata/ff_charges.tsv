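residue	atom	charge	type
ALA	N	-0.4157	N
ALA	H	0.2719	H
ALA	CA	0.0337	CT
ALA	HA	0.0823	H1
ALA	CB	-0.1825	CT
ALA	HB1	0.0603	HC
ALA	HB2	0.0603	HC
ALA	HB3	0.0603	HC
ALA	C	0.5973	C
ALA	O	-0.5679	O
GLY	N	-0.4157	N
GLY	H	0.2719	H
GLY	CA	-0.0252	CT
GLY	HA2	0.0698	H1
GLY	HA3	0.0698	H1
GLY	C	0.5973	C
GLY	O	-0.5679	O
SER	N	-0.4157	N
SER	H	0.2719	H
SER	CA	-0.0249	CT
SER	HA	0.0843	H1
SER	CB	0.2117	CT
SER	HB2	0.0352	H1
SER	HB3	0.0352	H1
SER	OG	-0.6546	OH
SER	HG	0.4275	HO
SER	C	0.5973	C
SER	O	-0.5679	O
THR	N	-0.4157	N
THR	H	0.2719	H
THR	CA	-0.0389	CT
THR	HA	0.1007	H1
THR	CB	0.3654	CT
THR	HB	0.0043	H1
THR	CG2	-0.2438	CT
THR	HG21	0.0642	HC
THR	HG22	0.0642	HC
THR	HG23	0.0642	HC
THR	OG1	-0.6761	OH
THR	HG1	0.4102	HO
THR	C	0.5973	C
THR	O	-0.5679	O
CYS	N	-0.4157	N
CYS	H	0.2719	H
CYS	CA	0.0213	CT
CYS	HA	0.1124	H1
CYS	CB	-0.1231	CT
CYS	HB2	0.1112	H1
CYS	HB3	0.1112	H1
CYS	SG	-0.3119	SH
CYS	HG	0.1933	HS
CYS	C	0.5973	C
CYS	O	-0.5679	O
VAL	N	-0.4157	N
VAL	H	0.2719	H
VAL	CA	-0.0875	CT
VAL	HA	0.0969	H1
VAL	CB	0.2985	CT
VAL	HB	-0.0297	HC
VAL	CG1	-0.3192	CT
VAL	HG11	0.0791	HC
VAL	HG12	0.0791	HC
VAL	HG13	0.0791	HC
VAL	CG2	-0.3192	CT
VAL	HG21	0.0791	HC
VAL	HG22	0.0791	HC
VAL	HG23	0.0791	HC
VAL	C	0.5973	C
VAL	O	-0.5679	O
LEU	N	-0.4157	N
LEU	H	0.2719	H
LEU	CA	-0.0518	CT
LEU	HA	0.0922	H1
LEU	CB	-0.1102	CT
LEU	HB2	0.0457	HC
LEU	HB3	0.0457	HC
LEU	CG	0.3531	CT
LEU	HG	-0.0361	HC
LEU	CD1	-0.4121	CT
LEU	HD11	0.1000	HC
LEU	HD12	0.1000	HC
LEU	HD13	0.1000	HC
LEU	CD2	-0.4121	CT
LEU	HD21	0.1000	HC
LEU	HD22	0.1000	HC
LEU	HD23	0.1000	HC
LEU	C	0.5973	C
LEU	O	-0.5679	O
ILE	N	-0.4157	N
ILE	H	0.2719	H
ILE	CA	-0.0597	CT
ILE	HA	0.0869	H1
ILE	CB	0.1303	CT
ILE	HB	0.0187	HC
ILE	CG2	-0.3204	CT
ILE	HG21	0.0882	HC
ILE	HG22	0.0882	HC
ILE	HG23	0.0882	HC
ILE	CG1	-0.0430	CT
ILE	HG12	0.0236	HC
ILE	HG13	0.0236	HC
ILE	CD1	-0.0660	CT
ILE	HD11	0.0186	HC
ILE	HD12	0.0186	HC
ILE	HD13	0.0186	HC
ILE	C	0.5973	C
ILE	O	-0.5679	O
MET	N	-0.4157	N
MET	H	0.2719	H
MET	CA	-0.0237	CT
MET	HA	0.0880	H1
MET	CB	0.0342	CT
MET	HB2	0.0241	HC
MET	HB3	0.0241	HC
MET	CG	0.0018	CT
MET	HG2	0.0440	H1
MET	HG3	0.0440	H1
MET	SD	-0.2737	S
MET	CE	-0.0536	CT
MET	HE1	0.0684	H1
MET	HE2	0.0684	H1
MET	HE3	0.0684	H1
MET	C	0.5973	C
MET	O	-0.5679	O
PHE	N	-0.4157	N
PHE	H	0.2719	H
PHE	CA	-0.0024	CT
PHE	HA	0.0978	H1
PHE	CB	-0.0343	CT
PHE	HB2	0.0295	HC
PHE	HB3	0.0295	HC
PHE	CG	0.0118	CA
PHE	CD1	-0.1256	CA
PHE	CD2	-0.1256	CA
PHE	HD1	0.1330	HA
PHE	HD2	0.1330	HA
PHE	CE1	-0.1704	CA
PHE	CE2	-0.1704	CA
PHE	HE1	0.1430	HA
PHE	HE2	0.1430	HA
PHE	CZ	-0.1072	CA
PHE	HZ	0.1297	HA
PHE	C	0.5973	C
PHE	O	-0.5679	O
TYR	N	-0.4157	N
TYR	H	0.2719	H
TYR	CA	-0.0014	CT
TYR	HA	0.0876	H1
TYR	CB	-0.0152	CT
TYR	HB2	0.0295	HC
TYR	HB3	0.0295	HC
TYR	CG	-0.0011	CA
TYR	CD1	-0.1906	CA
TYR	CD2	-0.1906	CA
TYR	HD1	0.1699	HA
TYR	HD2	0.1699	HA
TYR	CE1	-0.2341	CA
TYR	CE2	-0.2341	CA
TYR	HE1	0.1656	HA
TYR	HE2	0.1656	HA
TYR	CZ	0.3226	C
TYR	OH	-0.5579	OH
TYR	HH	0.3992	HO
TYR	C	0.5973	C
TYR	O	-0.5679	O
TRP	N	-0.4157	N
TRP	H	0.2719	H
TRP	CA	-0.0275	CT
TRP	HA	0.1123	H1
TRP	CB	-0.0050	CT
TRP	HB2	0.0339	HC
TRP	HB3	0.0339	HC
TRP	CG	-0.1415	C*
TRP	CD1	-0.1638	CW
TRP	HD1	0.2062	H4
TRP	NE1	-0.3418	NA
TRP	HE1	0.3412	H
TRP	CE2	0.1380	CN
TRP	CZ2	-0.2601	CA
TRP	HZ2	0.1572	HA
TRP	CH2	-0.1134	CA
TRP	HH2	0.1417	HA
TRP	CZ3	-0.1972	CA
TRP	HZ3	0.1447	HA
TRP	CE3	-0.2387	CA
TRP	HE3	0.1700	HA
TRP	CD2	0.1243	CB
TRP	C	0.5973	C
TRP	O	-0.5679	O
ASN	N	-0.4157	N
ASN	H	0.2719	H
ASN	CA	0.0143	CT
ASN	HA	0.1048	H1
ASN	CB	-0.2041	CT
ASN	HB2	0.0797	HC
ASN	HB3	0.0797	HC
ASN	CG	0.7130	C
ASN	OD1	-0.5931	O
ASN	ND2	-0.9191	N
ASN	HD21	0.4196	H
ASN	HD22	0.4196	H
ASN	C	0.5973	C
ASN	O	-0.5679	O
GLN	N	-0.4157	N
GLN	H	0.2719	H
GLN	CA	-0.0031	CT
GLN	HA	0.0850	H1
GLN	CB	-0.0036	CT
GLN	HB2	0.0171	HC
GLN	HB3	0.0171	HC
GLN	CG	-0.0645	CT
GLN	HG2	0.0352	HC
GLN	HG3	0.0352	HC
GLN	CD	0.6951	C
GLN	OE1	-0.6086	O
GLN	NE2	-0.9407	N
GLN	HE21	0.4251	H
GLN	HE22	0.4251	H
GLN	C	0.5973	C
GLN	O	-0.5679	O
ASP	N	-0.5163	N
ASP	H	0.2936	H
ASP	CA	0.0381	CT
ASP	HA	0.0880	H1
ASP	CB	-0.0303	CT
ASP	HB2	-0.0122	HC
ASP	HB3	-0.0122	HC
ASP	CG	0.7994	C
ASP	OD1	-0.8014	O2
ASP	OD2	-0.8014	O2
ASP	C	0.5366	C
ASP	O	-0.5819	O
GLU	N	-0.5163	N
GLU	H	0.2936	H
GLU	CA	0.0397	CT
GLU	HA	0.1105	H1
GLU	CB	0.0560	CT
GLU	HB2	-0.0173	HC
GLU	HB3	-0.0173	HC
GLU	CG	0.0136	CT
GLU	HG2	-0.0425	HC
GLU	HG3	-0.0425	HC
GLU	CD	0.8054	C
GLU	OE1	-0.8188	O2
GLU	OE2	-0.8188	O2
GLU	C	0.5366	C
GLU	O	-0.5819	O
LYS	N	-0.3479	N
LYS	H	0.2747	H
LYS	CA	-0.2400	CT
LYS	HA	0.1426	H1
LYS	CB	-0.0094	CT
LYS	HB2	0.0362	HC
LYS	HB3	0.0362	HC
LYS	CG	0.0187	CT
LYS	HG2	0.0103	HC
LYS	HG3	0.0103	HC
LYS	CD	-0.0479	CT
LYS	HD2	0.0621	HC
LYS	HD3	0.0621	HC
LYS	CE	-0.0143	CT
LYS	HE2	0.1135	HP
LYS	HE3	0.1135	HP
LYS	NZ	-0.3854	N3
LYS	HZ1	0.3400	H
LYS	HZ2	0.3400	H
LYS	HZ3	0.3400	H
LYS	C	0.7341	C
LYS	O	-0.5894	O
ARG	N	-0.3479	N
ARG	H	0.2747	H
ARG	CA	-0.2637	CT
ARG	HA	0.1560	H1
ARG	CB	-0.0007	CT
ARG	HB2	0.0327	HC
ARG	HB3	0.0327	HC
ARG	CG	0.0390	CT
ARG	HG2	0.0285	HC
ARG	HG3	0.0285	HC
ARG	CD	0.0486	CT
ARG	HD2	0.0687	H1
ARG	HD3	0.0687	H1
ARG	NE	-0.5295	N2
ARG	HE	0.3456	H
ARG	CZ	0.8076	CA
ARG	NH1	-0.8627	N2
ARG	NH2	-0.8627	N2
ARG	HH11	0.4478	H
ARG	HH12	0.4478	H
ARG	HH21	0.4478	H
ARG	HH22	0.4478	H
ARG	C	0.7341	C
ARG	O	-0.5894	O
HIS	N	-0.4157	N
HIS	H	0.2719	H
HIS	CA	-0.0581	CT
HIS	HA	0.1360	H1
HIS	CB	-0.0074	CT
HIS	HB2	0.0367	HC
HIS	HB3	0.0367	HC
HIS	CG	0.1868	CC
HIS	ND1	-0.5432	NB
HIS	CD2	-0.2207	CW
HIS	HD2	0.1862	H4
HIS	CE1	0.1635	CR
HIS	HE1	0.1435	H5
HIS	NE2	-0.2795	NA
HIS	HE2	0.3339	H
HIS	C	0.5973	C
HIS	O	-0.5679	O
PRO	N	-0.2548	N
PRO	CD	0.0192	CT
PRO	HD2	0.0391	H1
PRO	HD3	0.0391	H1
PRO	CG	0.0189	CT
PRO	HG2	0.0213	HC
PRO	HG3	0.0213	HC
PRO	CB	-0.0070	CT
PRO	HB2	0.0253	HC
PRO	HB3	0.0253	HC
PRO	CA	-0.0266	CT
PRO	HA	0.0641	H1
PRO	C	0.5896	C
PRO	O	-0.5748	O
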