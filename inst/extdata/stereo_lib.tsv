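kind	restype	a1	a2	a3	ideal	sd
bond	peptide	N	CA	.	1.458	0.019
bond	peptide	CA	C	.	1.525	0.021
bond	peptide	C	O	.	1.231	0.020
bond	peptide	CA	CB	.	1.530	0.025
bond	peptide	C	+N	.	1.329	0.014
angle	peptide	N	CA	C	111.0	2.8
angle	peptide	CA	C	O	120.1	2.1
angle	peptide	CA	C	+N	116.2	2.0
angle	peptide	C	+N	+CA	121.7	1.8
bond	nucleotide	P	OP1	.	1.485	0.017
bond	nucleotide	P	OP2	.	1.485	0.017
bond	nucleotide	P	O5'	.	1.593	0.010
bond	nucleotide	O5'	C5'	.	1.440	0.016
bond	nucleotide	C5'	C4'	.	1.510	0.013
bond	nucleotide	C4'	C3'	.	1.524	0.011
bond	nucleotide	C4'	O4'	.	1.453	0.012
bond	nucleotide	O4'	C1'	.	1.414	0.012
bond	nucleotide	C1'	C2'	.	1.528	0.010
bond	nucleotide	C2'	C3'	.	1.525	0.011
bond	nucleotide	C2'	O2'	.	1.413	0.013
bond	nucleotide	C3'	O3'	.	1.423	0.014
bond	nucleotide	O3'	+P	.	1.607	0.012
angle	nucleotide	O5'	C5'	C4'	111.5	1.6
angle	nucleotide	C5'	C4'	C3'	115.5	1.5
angle	nucleotide	C4'	C3'	O3'	110.3	2.0
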