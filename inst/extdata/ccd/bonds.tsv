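comp	atom1	atom2
BNZ	C1	C2
BNZ	C2	C3
BNZ	C3	C4
BNZ	C4	C5
BNZ	C5	C6
BNZ	C6	C1
GOL	C1	O1
GOL	C1	C2
GOL	C2	O2
GOL	C2	C3
GOL	C3	O3
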