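from	to	sign
H	M	1
E	L	1
K	N	1
D	H	1
A	I	1
J	L	1
B	O	1
H	J	1
B	N	1
F	H	1
A	O	-1
D	O	-1
D	L	-1
F	M	-1
E	J	-1
G	M	-1
B	G	-1
C	H	-1
A	M	-1
L	M	-1
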