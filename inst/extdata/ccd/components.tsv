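comp	type	parent	one_letter
ALA	peptide		A
ARG	peptide		R
ASN	peptide		N
ASP	peptide		D
CYS	peptide		C
GLN	peptide		Q
GLU	peptide		E
GLY	peptide		G
HIS	peptide		H
ILE	peptide		I
LEU	peptide		L
LYS	peptide		K
MET	peptide		M
PHE	peptide		F
PRO	peptide		P
SER	peptide		S
THR	peptide		T
TRP	peptide		W
TYR	peptide		Y
VAL	peptide		V
A	nucleotide		A
C	nucleotide		C
G	nucleotide		G
U	nucleotide		U
DA	nucleotide		A
DC	nucleotide		C
DG	nucleotide		G
DT	nucleotide		T
SEP	peptide	SER	S
TPO	peptide	THR	T
MSE	peptide	MET	M
BNZ	nonpolymer		
GOL	nonpolymer		
MG	nonpolymer		
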