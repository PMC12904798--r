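comp	atom	elem
ALA	N	N
ALA	CA	C
ALA	C	C
ALA	O	O
ALA	CB	C
ARG	N	N
ARG	CA	C
ARG	C	C
ARG	O	O
ARG	CB	C
ARG	CG	C
ARG	CD	C
ARG	NE	N
ARG	CZ	C
ARG	NH1	N
ARG	NH2	N
ASN	N	N
ASN	CA	C
ASN	C	C
ASN	O	O
ASN	CB	C
ASN	CG	C
ASN	OD1	O
ASN	ND2	N
ASP	N	N
ASP	CA	C
ASP	C	C
ASP	O	O
ASP	CB	C
ASP	CG	C
ASP	OD1	O
ASP	OD2	O
CYS	N	N
CYS	CA	C
CYS	C	C
CYS	O	O
CYS	CB	C
CYS	SG	S
GLN	N	N
GLN	CA	C
GLN	C	C
GLN	O	O
GLN	CB	C
GLN	CG	C
GLN	CD	C
GLN	OE1	O
GLN	NE2	N
GLU	N	N
GLU	CA	C
GLU	C	C
GLU	O	O
GLU	CB	C
GLU	CG	C
GLU	CD	C
GLU	OE1	O
GLU	OE2	O
GLY	N	N
GLY	CA	C
GLY	C	C
GLY	O	O
HIS	N	N
HIS	CA	C
HIS	C	C
HIS	O	O
HIS	CB	C
HIS	CG	C
HIS	ND1	N
HIS	CD2	C
HIS	CE1	C
HIS	NE2	N
ILE	N	N
ILE	CA	C
ILE	C	C
ILE	O	O
ILE	CB	C
ILE	CG1	C
ILE	CG2	C
ILE	CD1	C
LEU	N	N
LEU	CA	C
LEU	C	C
LEU	O	O
LEU	CB	C
LEU	CG	C
LEU	CD1	C
LEU	CD2	C
LYS	N	N
LYS	CA	C
LYS	C	C
LYS	O	O
LYS	CB	C
LYS	CG	C
LYS	CD	C
LYS	CE	C
LYS	NZ	N
MET	N	N
MET	CA	C
MET	C	C
MET	O	O
MET	CB	C
MET	CG	C
MET	SD	S
MET	CE	C
PHE	N	N
PHE	CA	C
PHE	C	C
PHE	O	O
PHE	CB	C
PHE	CG	C
PHE	CD1	C
PHE	CD2	C
PHE	CE1	C
PHE	CE2	C
PHE	CZ	C
PRO	N	N
PRO	CA	C
PRO	C	C
PRO	O	O
PRO	CB	C
PRO	CG	C
PRO	CD	C
SER	N	N
SER	CA	C
SER	C	C
SER	O	O
SER	CB	C
SER	OG	O
THR	N	N
THR	CA	C
THR	C	C
THR	O	O
THR	CB	C
THR	OG1	O
THR	CG2	C
TRP	N	N
TRP	CA	C
TRP	C	C
TRP	O	O
TRP	CB	C
TRP	CG	C
TRP	CD1	C
TRP	CD2	C
TRP	NE1	N
TRP	CE2	C
TRP	CE3	C
TRP	CZ2	C
TRP	CZ3	C
TRP	CH2	C
TYR	N	N
TYR	CA	C
TYR	C	C
TYR	O	O
TYR	CB	C
TYR	CG	C
TYR	CD1	C
TYR	CD2	C
TYR	CE1	C
TYR	CE2	C
TYR	CZ	C
TYR	OH	O
VAL	N	N
VAL	CA	C
VAL	C	C
VAL	O	O
VAL	CB	C
VAL	CG1	C
VAL	CG2	C
A	P	P
A	OP1	O
A	OP2	O
A	O5'	O
A	C5'	C
A	C4'	C
A	O4'	O
A	C3'	C
A	O3'	O
A	C2'	C
A	O2'	O
A	C1'	C
A	N9	N
A	C8	C
A	N7	N
A	C5	C
A	C6	C
A	N6	N
A	N1	N
A	C2	C
A	N3	N
A	C4	C
C	P	P
C	OP1	O
C	OP2	O
C	O5'	O
C	C5'	C
C	C4'	C
C	O4'	O
C	C3'	C
C	O3'	O
C	C2'	C
C	O2'	O
C	C1'	C
C	N1	N
C	C2	C
C	O2	O
C	N3	N
C	C4	C
C	N4	N
C	C5	C
C	C6	C
G	P	P
G	OP1	O
G	OP2	O
G	O5'	O
G	C5'	C
G	C4'	C
G	O4'	O
G	C3'	C
G	O3'	O
G	C2'	C
G	O2'	O
G	C1'	C
G	N9	N
G	C8	C
G	N7	N
G	C5	C
G	C6	C
G	O6	O
G	N1	N
G	C2	C
G	N2	N
G	N3	N
G	C4	C
U	P	P
U	OP1	O
U	OP2	O
U	O5'	O
U	C5'	C
U	C4'	C
U	O4'	O
U	C3'	C
U	O3'	O
U	C2'	C
U	O2'	O
U	C1'	C
U	N1	N
U	C2	C
U	O2	O
U	N3	N
U	C4	C
U	O4	O
U	C5	C
U	C6	C
DA	P	P
DA	OP1	O
DA	OP2	O
DA	O5'	O
DA	C5'	C
DA	C4'	C
DA	O4'	O
DA	C3'	C
DA	O3'	O
DA	C2'	C
DA	C1'	C
DA	N9	N
DA	C8	C
DA	N7	N
DA	C5	C
DA	C6	C
DA	N6	N
DA	N1	N
DA	C2	C
DA	N3	N
DA	C4	C
DC	P	P
DC	OP1	O
DC	OP2	O
DC	O5'	O
DC	C5'	C
DC	C4'	C
DC	O4'	O
DC	C3'	C
DC	O3'	O
DC	C2'	C
DC	C1'	C
DC	N1	N
DC	C2	C
DC	O2	O
DC	N3	N
DC	C4	C
DC	N4	N
DC	C5	C
DC	C6	C
DG	P	P
DG	OP1	O
DG	OP2	O
DG	O5'	O
DG	C5'	C
DG	C4'	C
DG	O4'	O
DG	C3'	C
DG	O3'	O
DG	C2'	C
DG	C1'	C
DG	N9	N
DG	C8	C
DG	N7	N
DG	C5	C
DG	C6	C
DG	O6	O
DG	N1	N
DG	C2	C
DG	N2	N
DG	N3	N
DG	C4	C
DT	P	P
DT	OP1	O
DT	OP2	O
DT	O5'	O
DT	C5'	C
DT	C4'	C
DT	O4'	O
DT	C3'	C
DT	O3'	O
DT	C2'	C
DT	C1'	C
DT	N1	N
DT	C2	C
DT	O2	O
DT	N3	N
DT	C4	C
DT	O4	O
DT	C5	C
DT	C7	C
DT	C6	C
SEP	N	N
SEP	CA	C
SEP	C	C
SEP	O	O
SEP	CB	C
SEP	OG	O
SEP	P	P
SEP	O1P	O
SEP	O2P	O
SEP	O3P	O
TPO	N	N
TPO	CA	C
TPO	C	C
TPO	O	O
TPO	CB	C
TPO	OG1	O
TPO	CG2	C
TPO	P	P
TPO	O1P	O
TPO	O2P	O
TPO	O3P	O
MSE	N	N
MSE	CA	C
MSE	C	C
MSE	O	O
MSE	CB	C
MSE	CG	C
MSE	SE	SE
MSE	CE	C
BNZ	C1	C
BNZ	C2	C
BNZ	C3	C
BNZ	C4	C
BNZ	C5	C
BNZ	C6	C
GOL	C1	C
GOL	O1	O
GOL	C2	C
GOL	O2	O
GOL	C3	C
GOL	O3	O
MG	MG	MG
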